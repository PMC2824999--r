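# Mass attenuation coefficients (cm^2/g) for P (Z=15, A=30.974), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	48.6227	0.186786	0.484396	0
0.010873643	37.2959	0.186188	0.426579	0
0.01182361	28.6077	0.185543	0.375664	0
0.012856571	21.9434	0.184849	0.330825	0
0.013979776	16.8316	0.184101	0.291339	0
0.015	13.4668	0.18343	0.261804	0
0.015201108	12.9026	0.183298	0.256381	0
0.016529142	9.85808	0.182435	0.22476	0
0.017973198	7.53196	0.181508	0.19704	0
0.019543413	5.7547	0.180515	0.172738	0
0.02	5.34312	0.180229	0.166581	0
0.021250809	4.38689	0.179451	0.150521	0
0.02310737	3.3413	0.178313	0.130861	0
0.025126128	2.54493	0.177098	0.113768	0
0.027321253	1.93836	0.175801	0.0989086	0
0.029708154	1.47637	0.174419	0.0859896	0
0.03	1.43019	0.174252	0.0845962	0
0.032303585	1.12191	0.17295	0.0741445	0
0.035125763	0.85229	0.171389	0.0638614	0
0.038194499	0.647467	0.169735	0.0550045	0
0.04	0.556405	0.168782	0.0506573	0
0.041531333	0.49156	0.167985	0.0472542	0
0.045159687	0.372908	0.166137	0.0404675	0
0.04910503	0.282897	0.16419	0.0346555	0
0.05	0.266536	0.163757	0.033516	0
0.053395054	0.214506	0.162142	0.0297228	0
0.058059873	0.162626	0.159994	0.0255027	0
0.06	0.145882	0.159124	0.0240153	0
0.06313223	0.123249	0.157746	0.0218256	0
0.06864773	0.0933846	0.155398	0.0186478	0
0.074645088	0.0707565	0.152954	0.0159326	0
0.08	0.056245	0.15086	0.013988	0
0.0811664	0.053622	0.150415	0.0135886	0
0.088257442	0.040675	0.147785	0.0114913	0
0.095967988	0.0308541	0.145069	0.00971778	0
0.1	0.0269365	0.143704	0.00894938	0
0.10435216	0.0234044	0.142272	0.00824388	0
0.11346881	0.0177534	0.139399	0.00701485	0
0.12338193	0.0134669	0.136458	0.00596905	0
0.1341611	0.0102153	0.133455	0.00507916	0
0.14588198	0.00774885	0.130399	0.00432194	0
0.15	0.00706885	0.129372	0.00409615	0
0.15862685	0.0058779	0.127297	0.00366096	0
0.17248517	0.00445869	0.124158	0.00309408	0
0.1875542	0.00338214	0.12099	0.00261498	0
0.2	0.00273608	0.118546	0.00229838	0
0.20393974	0.00256553	0.117802	0.0022091	0
0.22175678	0.00194608	0.114602	0.00186357	0
0.24113039	0.0014762	0.111399	0.00157208	0
0.26219657	0.00111978	0.108199	0.00132618	0
0.28510318	0.000849408	0.105011	0.00111874	0
0.3	0.00071802	0.10308	0.00100881	0
0.310011	0.000644319	0.101839	0.000943097	0
0.33709488	0.000488749	0.0986917	0.000794166	0
0.36654493	0.000370741	0.0955728	0.000668753	0
0.39856785	0.000281226	0.0924873	0.000563146	0
0.4	0.000277918	0.092356	0.000559016	0
0.43338843	0.000213324	0.0894392	0.000541345	0
0.47125109	0.000161818	0.086432	0.00052348	0
0.5	0.000133099	0.084332	0.000511206	0
0.511	0.000123877	0.083566	0.000487936	0
0.51242159	0.000122747	0.0834684	0.000485042	0
0.55718892	9.31098e-05	0.080551	0.00040542	0
0.6	7.2933e-05	0.0780125	0.000346002	0
0.60586731	7.06285e-05	0.0776816	0.000343073	0
0.65879846	5.35754e-05	0.074862	0.000318864	0
0.71635389	4.06397e-05	0.0720936	0.000296363	0
0.77893761	3.08273e-05	0.0693774	0.00027545	0
0.8	2.82295e-05	0.0685233	0.000269103	0
0.84698892	2.33841e-05	0.0667146	0.000277265	0
0.92098547	1.7738e-05	0.0641061	0.000289692	0
1	1.35195e-05	0.0615964	0.000302447	0
1.0014467	1.34552e-05	0.0615528	0.000302331	0
1.022	1.25828e-05	0.0609418	0.000300705	2.69028e-21
1.0889373	1.02064e-05	0.0590555	0.000295687	8.71334e-08
1.17	8.0536e-06	0.0569599	0.000290107	9.41766e-07
1.1840715	7.74211e-06	0.0566151	0.000289189	1.23673e-06
1.25	6.47468e-06	0.055067	0.000285061	3.44315e-06
1.287517	5.87279e-06	0.0542324	0.000307296	5.43784e-06
1.33	5.27627e-06	0.0533246	0.000333707	8.4879e-06
1.4	4.45481e-06	0.0519082	0.000380139	1.569e-05
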