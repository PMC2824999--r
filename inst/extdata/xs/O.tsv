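# Mass attenuation coefficients (cm^2/g) for O (Z=8, A=15.999), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	5.56208	0.192862	0.194806	0
0.010873643	4.26638	0.192245	0.171554	0
0.01182361	3.27251	0.191579	0.151078	0
0.012856571	2.51017	0.190862	0.133046	0
0.013979776	1.92542	0.190091	0.117166	0
0.015	1.5405	0.189397	0.105288	0
0.015201108	1.47596	0.189261	0.103107	0
0.016529142	1.12769	0.18837	0.0903901	0
0.017973198	0.861602	0.187413	0.0792419	0
0.019543413	0.658297	0.186387	0.0694686	0
0.02	0.611214	0.186092	0.0669925	0
0.021250809	0.501828	0.185289	0.060534	0
0.02310737	0.382221	0.184114	0.0526273	0
0.025126128	0.291122	0.182859	0.0457534	0
0.027321253	0.221735	0.18152	0.0397773	0
0.029708154	0.168886	0.180093	0.0345818	0
0.03	0.163604	0.179921	0.0340214	0
0.032303585	0.128338	0.178576	0.0298181	0
0.035125763	0.0974959	0.176965	0.0256827	0
0.038194499	0.0740656	0.175257	0.0221208	0
0.04	0.0636487	0.174273	0.0203725	0
0.041531333	0.056231	0.17345	0.0190038	0
0.045159687	0.042658	0.171542	0.0162745	0
0.04910503	0.0323613	0.169531	0.0139371	0
0.05	0.0304898	0.169084	0.0134789	0
0.053395054	0.0245379	0.167417	0.0119534	0
0.058059873	0.0186033	0.165199	0.0102562	0
0.06	0.0166878	0.1643	0.00965804	0
0.06313223	0.0140988	0.162877	0.00877745	0
0.06864773	0.0106825	0.160454	0.00749943	0
0.074645088	0.00809404	0.15793	0.00640749	0
0.08	0.00643402	0.155768	0.00562546	0
0.0811664	0.00613397	0.155308	0.00546482	0
0.088257442	0.00465293	0.152593	0.00462139	0
0.095967988	0.00352949	0.149788	0.00390812	0
0.1	0.00308134	0.148379	0.0035991	0
0.10435216	0.0026773	0.1469	0.00331538	0
0.11346881	0.00203087	0.143934	0.00282111	0
0.12338193	0.00154052	0.140897	0.00240052	0
0.1341611	0.00116856	0.137797	0.00204265	0
0.14588198	0.000886412	0.134641	0.00173812	0
0.15	0.000808626	0.133581	0.00164732	0
0.15862685	0.000672389	0.131438	0.0014723	0
0.17248517	0.000510042	0.128197	0.00124432	0
0.1875542	0.000386893	0.124926	0.00105165	0
0.2	0.000312988	0.122402	0.00092432	0
0.20393974	0.000293478	0.121634	0.000888418	0
0.22175678	0.000222618	0.118331	0.000749456	0
0.24113039	0.000168867	0.115023	0.00063223	0
0.26219657	0.000128094	0.111719	0.000533339	0
0.28510318	9.71661e-05	0.108427	0.000449917	0
0.3	8.21363e-05	0.106433	0.000405706	0
0.310011	7.37055e-05	0.105152	0.000379278	0
0.33709488	5.59094e-05	0.101902	0.000319383	0
0.36654493	4.24101e-05	0.0986819	0.000268947	0
0.39856785	3.21703e-05	0.095496	0.000226476	0
0.4	3.17918e-05	0.0953604	0.000224815	0
0.43338843	2.44028e-05	0.0923488	0.000217709	0
0.47125109	1.85108e-05	0.0892437	0.000210524	0
0.5	1.52255e-05	0.0870755	0.000205588	0
0.511	1.41707e-05	0.0862845	0.000196229	0
0.51242159	1.40414e-05	0.0861838	0.000195066	0
0.55718892	1.06511e-05	0.0831714	0.000163045	0
0.6	8.34302e-06	0.0805503	0.000139149	0
0.60586731	8.0794e-06	0.0802087	0.000137971	0
0.65879846	6.12864e-06	0.0772974	0.000128235	0
0.71635389	4.64888e-06	0.0744388	0.000119186	0
0.77893761	3.52642e-06	0.0716343	0.000110776	0
0.8	3.22926e-06	0.0707525	0.000108223	0
0.84698892	2.67497e-06	0.0688849	0.000111505	0
0.92098547	2.0291e-06	0.0661915	0.000116503	0
1	1.54653e-06	0.0636002	0.000121633	0
1.0014467	1.53918e-06	0.0635551	0.000121586	0
1.022	1.43939e-06	0.0629244	0.000120932	1.48149e-21
1.0889373	1.16754e-06	0.0609766	0.000118914	4.79829e-08
1.17	9.21274e-07	0.0588129	0.00011667	5.18615e-07
1.1840715	8.85642e-07	0.0584568	0.000116301	6.81049e-07
1.25	7.40656e-07	0.0568584	0.000114641	1.89609e-06
1.287517	6.71805e-07	0.0559966	0.000123583	2.99453e-06
1.33	6.03568e-07	0.0550593	0.000134204	4.67415e-06
1.4	5.09598e-07	0.0535969	0.000152878	8.6402e-06
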