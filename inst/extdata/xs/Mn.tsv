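# Mass attenuation coefficients (cm^2/g) for Mn (Z=25, A=54.938), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	273.075	0.175516	0.979369	0
0.010873643	209.462	0.174954	0.862474	0
0.01182361	160.667	0.174348	0.759531	0
0.012856571	123.239	0.173696	0.668875	0
0.013979776	94.5302	0.172994	0.58904	0
0.015	75.6322	0.172362	0.529324	0
0.015201108	72.4638	0.172239	0.518361	0
0.016529142	55.3651	0.171428	0.454429	0
0.017973198	42.3011	0.170557	0.398382	0
0.019543413	32.3197	0.169624	0.349248	0
0.02	30.0081	0.169355	0.3368	0
0.021250809	24.6377	0.168624	0.30433	0
0.02310737	18.7655	0.167555	0.26458	0
0.025126128	14.2929	0.166412	0.230021	0
0.027321253	10.8863	0.165194	0.199977	0
0.029708154	8.29161	0.163896	0.173857	0
0.03	8.03227	0.163739	0.17104	0
0.032303585	6.30088	0.162515	0.149908	0
0.035125763	4.78665	0.161049	0.129117	0
0.038194499	3.63632	0.159494	0.11121	0
0.04	3.12489	0.158599	0.102421	0
0.041531333	2.76071	0.15785	0.0955402	0
0.045159687	2.09433	0.156114	0.0818187	0
0.04910503	1.58881	0.154284	0.0700679	0
0.05	1.49692	0.153877	0.067764	0
0.053395054	1.20471	0.15236	0.0600947	0
0.058059873	0.913345	0.150341	0.0515624	0
0.06	0.819302	0.149523	0.048555	0
0.06313223	0.692195	0.148228	0.0441279	0
0.06864773	0.524468	0.146022	0.0377028	0
0.074645088	0.397384	0.143725	0.0322131	0
0.08	0.315884	0.141758	0.0282815	0
0.0811664	0.301153	0.14134	0.027474	0
0.088257442	0.22844	0.138869	0.0232336	0
0.095967988	0.173283	0.136316	0.0196478	0
0.1	0.151281	0.135034	0.0180942	0
0.10435216	0.131444	0.133688	0.0166678	0
0.11346881	0.0997071	0.130989	0.0141829	0
0.12338193	0.075633	0.128225	0.0120684	0
0.1341611	0.0573715	0.125403	0.0102692	0
0.14588198	0.0435192	0.122531	0.00873826	0
0.15	0.0397002	0.121567	0.00828175	0
0.15862685	0.0330115	0.119616	0.00740188	0
0.17248517	0.0250409	0.116667	0.00625573	0
0.1875542	0.0189948	0.11369	0.00528706	0
0.2	0.0153664	0.111394	0.00464694	0
0.20393974	0.0144086	0.110695	0.00446645	0
0.22175678	0.0109296	0.107688	0.00376783	0
0.24113039	0.00829068	0.104678	0.00317848	0
0.26219657	0.00628891	0.101671	0.00268132	0
0.28510318	0.00477046	0.0986747	0.00226192	0
0.3	0.00403256	0.0968604	0.00203966	0
0.310011	0.00361864	0.0956949	0.00190679	0
0.33709488	0.00274492	0.0927371	0.00160567	0
0.36654493	0.00208216	0.0898064	0.00135211	0
0.39856785	0.00157943	0.0869071	0.00113859	0
0.4	0.00156085	0.0867837	0.00113024	0
0.43338843	0.00119808	0.0840429	0.00109451	0
0.47125109	0.000908802	0.0812171	0.00105839	0
0.5	0.00074751	0.0792439	0.00103358	0
0.511	0.000695721	0.0785241	0.000986527	0
0.51242159	0.000689373	0.0784324	0.000980677	0
0.55718892	0.000522925	0.075691	0.000819694	0
0.6	0.000409608	0.0733056	0.00069956	0
0.60586731	0.000396665	0.0729947	0.000693638	0
0.65879846	0.000300891	0.0703453	0.000644691	0
0.71635389	0.000228241	0.0677438	0.000599198	0
0.77893761	0.000173133	0.0651915	0.000556915	0
0.8	0.000158543	0.064389	0.000544083	0
0.84698892	0.00013133	0.0626894	0.000560584	0
0.92098547	9.96204e-05	0.0602383	0.000585709	0
1	7.59285e-05	0.05788	0.000611498	0
1.0014467	7.55672e-05	0.057839	0.000611263	0
1.022	7.0668e-05	0.0572649	0.000607978	4.21327e-21
1.0889373	5.73216e-05	0.0554924	0.00059783	1.3646e-07
1.17	4.52307e-05	0.0535233	0.00058655	1.47491e-06
1.1840715	4.34814e-05	0.0531992	0.000584693	1.93686e-06
1.25	3.63632e-05	0.0517446	0.000576348	5.39235e-06
1.287517	3.29828e-05	0.0509603	0.000621303	8.51625e-06
1.33	2.96327e-05	0.0501073	0.000674701	1.3293e-05
1.4	2.50192e-05	0.0487764	0.00076858	2.45722e-05
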