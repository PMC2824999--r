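# Mass attenuation coefficients (cm^2/g) for Cl (Z=17, A=35.457), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	74.6008	0.184926	0.578615	0
0.010873643	57.2223	0.184333	0.509553	0
0.01182361	43.8922	0.183695	0.448734	0
0.012856571	33.6674	0.183008	0.395174	0
0.013979776	25.8245	0.182268	0.348007	0
0.015	20.6618	0.181603	0.312727	0
0.015201108	19.7962	0.181472	0.306249	0
0.016529142	15.1251	0.180618	0.268478	0
0.017973198	11.5561	0.179701	0.235366	0
0.019543413	8.82933	0.178717	0.206337	0
0.02	8.19784	0.178434	0.198982	0
0.021250809	6.73071	0.177664	0.179799	0
0.02310737	5.1265	0.176537	0.156315	0
0.025126128	3.90464	0.175334	0.135897	0
0.027321253	2.974	0.17405	0.118147	0
0.029708154	2.26517	0.172682	0.102715	0
0.03	2.19432	0.172517	0.101051	0
0.032303585	1.72132	0.171227	0.0885662	0
0.035125763	1.30765	0.169682	0.0762831	0
0.038194499	0.993396	0.168045	0.0657034	0
0.04	0.853681	0.167101	0.0605106	0
0.041531333	0.754191	0.166312	0.0564455	0
0.045159687	0.572146	0.164483	0.0483388	0
0.04910503	0.434043	0.162555	0.0413964	0
0.05	0.408941	0.162126	0.0400352	0
0.053395054	0.329112	0.160528	0.0355042	0
0.058059873	0.249514	0.158401	0.0304632	0
0.06	0.223823	0.157539	0.0286865	0
0.06313223	0.189099	0.156175	0.0260709	0
0.06864773	0.143278	0.153851	0.0222749	0
0.074645088	0.10856	0.151431	0.0190316	0
0.08	0.0862956	0.149358	0.0167088	0
0.0811664	0.0822712	0.148917	0.0162317	0
0.088257442	0.0624069	0.146313	0.0137265	0
0.095967988	0.0473388	0.143624	0.011608	0
0.1	0.0413281	0.142273	0.0106901	0
0.10435216	0.0359089	0.140855	0.00984738	0
0.11346881	0.0272388	0.138011	0.0083793	0
0.12338193	0.020662	0.135099	0.00713008	0
0.1341611	0.0156732	0.132126	0.0060671	0
0.14588198	0.0118889	0.1291	0.00516259	0
0.15	0.0108456	0.128084	0.00489289	0
0.15862685	0.00901834	0.126029	0.00437305	0
0.17248517	0.00684088	0.122921	0.00369591	0
0.1875542	0.00518915	0.119785	0.00312362	0
0.2	0.00419791	0.117365	0.00274543	0
0.20393974	0.00393624	0.116629	0.0026388	0
0.22175678	0.00298584	0.113461	0.00222605	0
0.24113039	0.00226491	0.110289	0.00187786	0
0.26219657	0.00171805	0.107122	0.00158413	0
0.28510318	0.00130323	0.103965	0.00133635	0
0.3	0.00110164	0.102053	0.00120504	0
0.310011	0.000988567	0.100825	0.00112654	0
0.33709488	0.000749878	0.0977088	0.000948638	0
0.36654493	0.000568821	0.0946209	0.000798832	0
0.39856785	0.00043148	0.0915662	0.000672683	0
0.4	0.000426404	0.0914361	0.00066775	0
0.43338843	0.0003273	0.0885484	0.000646642	0
0.47125109	0.000248273	0.0855712	0.000625301	0
0.5	0.000204211	0.0834921	0.00061064	0
0.511	0.000190062	0.0827337	0.000582844	0
0.51242159	0.000188328	0.0826371	0.000579387	0
0.55718892	0.000142857	0.0797487	0.000484278	0
0.6	0.0001119	0.0772355	0.000413303	0
0.60586731	0.000108364	0.076908	0.000409804	0
0.65879846	8.21996e-05	0.0741165	0.000380886	0
0.71635389	6.23526e-05	0.0713755	0.000354008	0
0.77893761	4.72977e-05	0.0686864	0.000329027	0
0.8	4.3312e-05	0.0678409	0.000321446	0
0.84698892	3.58777e-05	0.0660501	0.000331195	0
0.92098547	2.72151e-05	0.0634676	0.000346039	0
1	2.07427e-05	0.0609829	0.000361275	0
1.0014467	2.0644e-05	0.0609397	0.000361137	0
1.022	1.93056e-05	0.0603349	0.000359195	3.01862e-21
1.0889373	1.56595e-05	0.0584673	0.0003532	9.77677e-08
1.17	1.23565e-05	0.0563926	0.000346536	1.0567e-06
1.1840715	1.18786e-05	0.0560512	0.000345438	1.38767e-06
1.25	9.93397e-06	0.0545186	0.000340508	3.86337e-06
1.287517	9.0105e-06	0.0536923	0.000367068	6.10151e-06
1.33	8.09529e-06	0.0527935	0.000398616	9.52382e-06
1.4	6.83493e-06	0.0513912	0.00045408	1.76049e-05
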