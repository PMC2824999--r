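# Mass attenuation coefficients (cm^2/g) for Si (Z=14, A=28.086), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	39.3108	0.19226	0.449572	0
0.010873643	30.1532	0.191644	0.395912	0
0.01182361	23.1289	0.19098	0.348657	0
0.012856571	17.741	0.190266	0.307042	0
0.013979776	13.6082	0.189497	0.270395	0
0.015	10.8877	0.188805	0.242982	0
0.015201108	10.4316	0.18867	0.23795	0
0.016529142	7.97013	0.187781	0.208602	0
0.017973198	6.08949	0.186827	0.182874	0
0.019543413	4.6526	0.185805	0.16032	0
0.02	4.31984	0.18551	0.154605	0
0.021250809	3.54674	0.18471	0.1397	0
0.02310737	2.7014	0.183539	0.121453	0
0.025126128	2.05754	0.182287	0.10559	0
0.027321253	1.56714	0.180953	0.091798	0
0.029708154	1.19363	0.179531	0.0798078	0
0.03	1.15629	0.179359	0.0785146	0
0.032303585	0.907048	0.178018	0.0688142	0
0.035125763	0.689065	0.176412	0.0592704	0
0.038194499	0.523469	0.17471	0.0510503	0
0.04	0.449846	0.173729	0.0470156	0
0.041531333	0.39742	0.172908	0.043857	0
0.045159687	0.301492	0.171006	0.0375583	0
0.04910503	0.228718	0.169002	0.0321641	0
0.05	0.215491	0.168556	0.0311066	0
0.053395054	0.173425	0.166894	0.027586	0
0.058059873	0.131481	0.164683	0.0236693	0
0.06	0.117943	0.163787	0.0222888	0
0.06313223	0.0996454	0.162369	0.0202566	0
0.06864773	0.0755002	0.159952	0.0173072	0
0.074645088	0.0572057	0.157436	0.0147872	0
0.08	0.0454733	0.155281	0.0129824	0
0.0811664	0.0433527	0.154823	0.0126117	0
0.088257442	0.0328852	0.152116	0.0106652	0
0.095967988	0.0249451	0.14932	0.00901916	0
0.1	0.0217778	0.147916	0.00830601	0
0.10435216	0.0189222	0.146441	0.00765122	0
0.11346881	0.0143534	0.143484	0.00651055	0
0.12338193	0.0108878	0.140457	0.00553993	0
0.1341611	0.00825896	0.137366	0.00471402	0
0.14588198	0.00626484	0.13422	0.00401123	0
0.15	0.00571507	0.133164	0.00380168	0
0.15862685	0.0047522	0.131027	0.00339778	0
0.17248517	0.00360479	0.127796	0.00287165	0
0.1875542	0.00273442	0.124536	0.00242699	0
0.2	0.00221208	0.12202	0.00213315	0
0.20393974	0.00207419	0.121254	0.00205029	0
0.22175678	0.00157338	0.117961	0.00172959	0
0.24113039	0.00119349	0.114663	0.00145906	0
0.26219657	0.000905324	0.11137	0.00123084	0
0.28510318	0.000686735	0.108088	0.00103832	0
0.3	0.00058051	0.1061	0.000936289	0
0.310011	0.000520924	0.104824	0.000875297	0
0.33709488	0.000395147	0.101584	0.000737073	0
0.36654493	0.000299739	0.0983736	0.000620677	0
0.39856785	0.000227368	0.0951976	0.000522661	0
0.4	0.000224693	0.0950625	0.000518828	0
0.43338843	0.00017247	0.0920602	0.000502428	0
0.47125109	0.000130827	0.0889649	0.000485847	0
0.5	0.000107608	0.0868034	0.000474455	0
0.511	0.000100153	0.0860149	0.000452858	0
0.51242159	9.92392e-05	0.0859145	0.000450172	0
0.55718892	7.5278e-05	0.0829116	0.000376274	0
0.6	5.89654e-05	0.0802987	0.000321128	0
0.60586731	5.71022e-05	0.0799581	0.000318409	0
0.65879846	4.3315e-05	0.0770559	0.000295941	0
0.71635389	3.28566e-05	0.0742063	0.000275057	0
0.77893761	2.49234e-05	0.0714105	0.000255648	0
0.8	2.28232e-05	0.0705314	0.000249757	0
0.84698892	1.89057e-05	0.0686697	0.000257332	0
0.92098547	1.43409e-05	0.0659847	0.000268866	0
1	1.09303e-05	0.0634014	0.000280704	0
1.0014467	1.08783e-05	0.0633566	0.000280596	0
1.022	1.01731e-05	0.0627278	0.000279088	2.58451e-21
1.0889373	8.25177e-06	0.0607861	0.00027443	8.37078e-08
1.17	6.51123e-06	0.0586291	0.000269251	9.0474e-07
1.1840715	6.25939e-06	0.0582742	0.000268399	1.18811e-06
1.25	5.23469e-06	0.0566808	0.000264568	3.30778e-06
1.287517	4.74807e-06	0.0558217	0.000285204	5.22405e-06
1.33	4.2658e-06	0.0548873	0.000309716	8.1542e-06
1.4	3.60165e-06	0.0534294	0.000352811	1.50731e-05
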