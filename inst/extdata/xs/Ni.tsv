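# Mass attenuation coefficients (cm^2/g) for Ni (Z=28, A=58.693), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	425.648	0.184002	1.21696	0
0.010873643	326.492	0.183412	1.07171	0
0.01182361	250.434	0.182777	0.943794	0
0.012856571	192.095	0.182093	0.831145	0
0.013979776	147.346	0.181357	0.731942	0
0.015	117.889	0.180695	0.657739	0
0.015201108	112.951	0.180566	0.644115	0
0.016529142	86.2986	0.179715	0.564674	0
0.017973198	65.9355	0.178803	0.49503	0
0.019543413	50.3772	0.177824	0.433976	0
0.02	46.7742	0.177542	0.418507	0
0.021250809	38.4032	0.176776	0.37816	0
0.02310737	29.2501	0.175655	0.328767	0
0.025126128	22.2786	0.174458	0.285825	0
0.027321253	16.9686	0.17318	0.248492	0
0.029708154	12.9243	0.171819	0.216035	0
0.03	12.52	0.171655	0.212534	0
0.032303585	9.82129	0.170372	0.186276	0
0.035125763	7.46103	0.168835	0.160441	0
0.038194499	5.66799	0.167205	0.13819	0
0.04	4.87082	0.166267	0.127268	0
0.041531333	4.30317	0.165481	0.118718	0
0.045159687	3.26448	0.163661	0.101668	0
0.04910503	2.4765	0.161743	0.0870664	0
0.05	2.33328	0.161316	0.0842036	0
0.053395054	1.8778	0.159726	0.0746737	0
0.058059873	1.42365	0.157609	0.0640714	0
0.06	1.27706	0.156752	0.0603345	0
0.06313223	1.07894	0.155394	0.0548334	0
0.06864773	0.817498	0.153082	0.0468495	0
0.074645088	0.61941	0.150674	0.0400281	0
0.08	0.492374	0.148612	0.0351427	0
0.0811664	0.469412	0.148173	0.0341392	0
0.088257442	0.356073	0.145582	0.0288701	0
0.095967988	0.2701	0.142907	0.0244143	0
0.1	0.235805	0.141562	0.0224839	0
0.10435216	0.204884	0.140151	0.0207114	0
0.11346881	0.155415	0.137321	0.0176237	0
0.12338193	0.11789	0.134424	0.0149963	0
0.1341611	0.089426	0.131466	0.0127606	0
0.14588198	0.0678342	0.128455	0.0108582	0
0.15	0.0618814	0.127444	0.0102909	0
0.15862685	0.0514557	0.125399	0.00919758	0
0.17248517	0.0390318	0.122307	0.00777338	0
0.1875542	0.0296076	0.119187	0.00656971	0
0.2	0.0239519	0.116779	0.0057743	0
0.20393974	0.0224589	0.116046	0.00555001	0
0.22175678	0.0170362	0.112894	0.00468191	0
0.24113039	0.0129228	0.109738	0.00394958	0
0.26219657	0.00980263	0.106586	0.00333181	0
0.28510318	0.0074358	0.103445	0.00281066	0
0.3	0.00628562	0.101543	0.00253448	0
0.310011	0.00564044	0.100321	0.00236938	0
0.33709488	0.00427856	0.0972206	0.00199521	0
0.36654493	0.00324551	0.0941482	0.00168013	0
0.39856785	0.00246188	0.0911087	0.00141481	0
0.4	0.00243292	0.0909793	0.00140444	0
0.43338843	0.00186746	0.088106	0.00136004	0
0.47125109	0.00141657	0.0851436	0.00131516	0
0.5	0.00116516	0.083075	0.00128432	0
0.511	0.00108443	0.0823204	0.00122586	0
0.51242159	0.00107454	0.0822243	0.00121859	0
0.55718892	0.000815092	0.0793503	0.00101855	0
0.6	0.000638463	0.0768497	0.000869274	0
0.60586731	0.000618289	0.0765237	0.000861915	0
0.65879846	0.000469004	0.0737462	0.000801093	0
0.71635389	0.000355764	0.0710189	0.000744564	0
0.77893761	0.000269865	0.0683433	0.000692023	0
0.8	0.000247124	0.0675019	0.000676078	0
0.84698892	0.000204706	0.0657201	0.000696582	0
0.92098547	0.00015528	0.0631505	0.000727803	0
1	0.000118351	0.0606782	0.000759848	0
1.0014467	0.000117788	0.0606353	0.000759556	0
1.022	0.000110151	0.0600335	0.000755473	4.947e-21
1.0889373	8.93482e-05	0.0581752	0.000742864	1.60225e-07
1.17	7.0502e-05	0.0561109	0.000728847	1.73176e-06
1.1840715	6.77752e-05	0.0557712	0.000726539	2.27416e-06
1.25	5.668e-05	0.0542462	0.00071617	6.33141e-06
1.287517	5.1411e-05	0.053424	0.000772031	9.99934e-06
1.33	4.6189e-05	0.0525297	0.000838384	1.56079e-05
1.4	3.89978e-05	0.0511345	0.000955038	2.88514e-05
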