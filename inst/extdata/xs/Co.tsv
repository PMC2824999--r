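# Mass attenuation coefficients (cm^2/g) for Co (Z=27, A=58.933), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	359.918	0.176708	1.10668	0
0.010873643	276.074	0.176142	0.974585	0
0.01182361	211.762	0.175532	0.858261	0
0.012856571	162.431	0.174875	0.755821	0
0.013979776	124.592	0.174168	0.665608	0
0.015	99.6846	0.173532	0.59813	0
0.015201108	95.5086	0.173408	0.585741	0
0.016529142	72.9722	0.172591	0.513499	0
0.017973198	55.7536	0.171715	0.450167	0
0.019543413	42.5979	0.170775	0.394646	0
0.02	39.5512	0.170504	0.380579	0
0.021250809	32.4729	0.169769	0.343889	0
0.02310737	24.7332	0.168692	0.298972	0
0.025126128	18.8383	0.167542	0.259921	0
0.027321253	14.3483	0.166315	0.225972	0
0.029708154	10.9285	0.165008	0.196456	0
0.03	10.5867	0.16485	0.193273	0
0.032303585	8.30467	0.163618	0.169394	0
0.035125763	6.30888	0.162142	0.145901	0
0.038194499	4.79273	0.160577	0.125666	0
0.04	4.11866	0.159675	0.115734	0
0.041531333	3.63866	0.158922	0.107959	0
0.045159687	2.76037	0.157173	0.0924541	0
0.04910503	2.09408	0.155331	0.0791758	0
0.05	1.97297	0.154921	0.0765725	0
0.053395054	1.58783	0.153394	0.0679063	0
0.058059873	1.2038	0.151362	0.0582648	0
0.06	1.07985	0.150538	0.0548665	0
0.06313223	0.912325	0.149234	0.049864	0
0.06864773	0.691258	0.147014	0.0426037	0
0.074645088	0.523759	0.144701	0.0364004	0
0.08	0.416341	0.14272	0.0319578	0
0.0811664	0.396925	0.142299	0.0310452	0
0.088257442	0.301088	0.139811	0.0262537	0
0.095967988	0.22839	0.137242	0.0222017	0
0.1	0.199391	0.135951	0.0204462	0
0.10435216	0.173246	0.134595	0.0188344	0
0.11346881	0.131416	0.131878	0.0160265	0
0.12338193	0.0996856	0.129095	0.0136372	0
0.1341611	0.0756166	0.126254	0.0116041	0
0.14588198	0.0573591	0.123363	0.00987412	0
0.15	0.0523256	0.122392	0.00935827	0
0.15862685	0.0435098	0.120428	0.00836403	0
0.17248517	0.0330044	0.117459	0.0070689	0
0.1875542	0.0250355	0.114462	0.00597431	0
0.2	0.0202532	0.11215	0.00525099	0
0.20393974	0.0189907	0.111446	0.00504703	0
0.22175678	0.0144054	0.108419	0.0042576	0
0.24113039	0.0109273	0.105388	0.00359165	0
0.26219657	0.00828889	0.102361	0.00302986	0
0.28510318	0.00628755	0.0993445	0.00255594	0
0.3	0.00531498	0.0975179	0.00230479	0
0.310011	0.00476943	0.0963445	0.00215465	0
0.33709488	0.00361785	0.0933667	0.00181439	0
0.36654493	0.00274433	0.090416	0.00152787	0
0.39856785	0.00208171	0.087497	0.00128659	0
0.4	0.00205722	0.0873728	0.00127716	0
0.43338843	0.00157909	0.0846134	0.00123679	0
0.47125109	0.00119782	0.0817684	0.00119597	0
0.5	0.000985232	0.0797818	0.00116793	0
0.511	0.000916972	0.0790571	0.00111476	0
0.51242159	0.000908606	0.0789648	0.00110815	0
0.55718892	0.000689224	0.0762048	0.000926244	0
0.6	0.00053987	0.0738032	0.000790495	0
0.60586731	0.000522812	0.0734902	0.000783802	0
0.65879846	0.000396579	0.0708228	0.000728493	0
0.71635389	0.000300826	0.0682037	0.000677086	0
0.77893761	0.000228192	0.0656341	0.000629307	0
0.8	0.000208963	0.0648261	0.000614807	0
0.84698892	0.000173095	0.0631149	0.000633453	0
0.92098547	0.000131301	0.0606472	0.000661844	0
1	0.000100075	0.0582728	0.000690985	0
1.0014467	9.95989e-05	0.0582316	0.00069072	0
1.022	9.31416e-05	0.0576537	0.000687007	4.58122e-21
1.0889373	7.55509e-05	0.0558691	0.000675541	1.48378e-07
1.17	5.96149e-05	0.0538866	0.000662794	1.60371e-06
1.1840715	5.73092e-05	0.0535604	0.000660695	2.10601e-06
1.25	4.79273e-05	0.0520958	0.000651266	5.86327e-06
1.287517	4.3472e-05	0.0513062	0.000702064	9.25999e-06
1.33	3.90564e-05	0.0504474	0.000762403	1.44539e-05
1.4	3.29757e-05	0.0491075	0.000868486	2.67181e-05
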