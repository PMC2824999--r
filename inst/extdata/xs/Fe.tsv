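# Mass attenuation coefficients (cm^2/g) for Fe (Z=26, A=55.845), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	320.495	0.179572	1.06272	0
0.010873643	245.835	0.178997	0.935875	0
0.01182361	188.567	0.178377	0.824171	0
0.012856571	144.64	0.17771	0.7258	0
0.013979776	110.945	0.176991	0.639171	0
0.015	88.7658	0.176346	0.574373	0
0.015201108	85.0471	0.176219	0.562476	0
0.016529142	64.9793	0.175389	0.493103	0
0.017973198	49.6467	0.174498	0.432287	0
0.019543413	37.932	0.173543	0.378971	0
0.02	35.219	0.173268	0.365463	0
0.021250809	28.916	0.172521	0.33023	0
0.02310737	22.0241	0.171427	0.287097	0
0.025126128	16.7748	0.170258	0.249597	0
0.027321253	12.7767	0.169011	0.216996	0
0.029708154	9.73145	0.167683	0.188653	0
0.03	9.42707	0.167523	0.185596	0
0.032303585	7.39502	0.16627	0.162666	0
0.035125763	5.61785	0.16477	0.140106	0
0.038194499	4.26776	0.16318	0.120675	0
0.04	3.66753	0.162264	0.111137	0
0.041531333	3.24011	0.161498	0.103671	0
0.045159687	2.45802	0.159721	0.0887819	0
0.04910503	1.8647	0.157849	0.076031	0
0.05	1.75687	0.157433	0.0735311	0
0.053395054	1.41391	0.155881	0.0652091	0
0.058059873	1.07195	0.153815	0.0559506	0
0.06	0.961574	0.152978	0.0526873	0
0.06313223	0.812394	0.151654	0.0478834	0
0.06864773	0.615542	0.149397	0.0409115	0
0.074645088	0.46639	0.147047	0.0349546	0
0.08	0.370737	0.145034	0.0306885	0
0.0811664	0.353448	0.144606	0.0298121	0
0.088257442	0.268108	0.142078	0.0252109	0
0.095967988	0.203374	0.139467	0.0213199	0
0.1	0.177551	0.138155	0.0196341	0
0.10435216	0.154269	0.136777	0.0180863	0
0.11346881	0.117021	0.134016	0.0153899	0
0.12338193	0.0887666	0.131188	0.0130955	0
0.1341611	0.067334	0.128301	0.0111432	0
0.14588198	0.0510763	0.125363	0.00948193	0
0.15	0.0465941	0.124376	0.00898657	0
0.15862685	0.038744	0.122381	0.00803181	0
0.17248517	0.0293893	0.119363	0.00678813	0
0.1875542	0.0222933	0.116317	0.00573702	0
0.2	0.0180348	0.113968	0.00504242	0
0.20393974	0.0169106	0.113253	0.00484657	0
0.22175678	0.0128276	0.110176	0.00408849	0
0.24113039	0.00973036	0.107097	0.00344899	0
0.26219657	0.00738098	0.104021	0.00290951	0
0.28510318	0.00559885	0.100955	0.00245442	0
0.3	0.00473281	0.0990988	0.00221324	0
0.310011	0.00424701	0.0979063	0.00206907	0
0.33709488	0.00322158	0.0948802	0.00174233	0
0.36654493	0.00244373	0.0918818	0.00146718	0
0.39856785	0.00185369	0.0889154	0.00123549	0
0.4	0.00183189	0.0887892	0.00122643	0
0.43338843	0.00140612	0.0859851	0.00118766	0
0.47125109	0.00106662	0.083094	0.00114847	0
0.5	0.000877315	0.0810751	0.00112154	0
0.511	0.000816533	0.0803387	0.00107049	0
0.51242159	0.000809083	0.0802449	0.00106414	0
0.55718892	0.000613731	0.0774401	0.000889454	0
0.6	0.000480736	0.0749997	0.000759097	0
0.60586731	0.000465546	0.0746816	0.00075267	0
0.65879846	0.00035314	0.0719709	0.000699557	0
0.71635389	0.000267875	0.0693093	0.000650193	0
0.77893761	0.000203197	0.066698	0.000604311	0
0.8	0.000186074	0.0658769	0.000590387	0
0.84698892	0.000154135	0.0641381	0.000608293	0
0.92098547	0.00011692	0.0616303	0.000635556	0
1	8.91135e-05	0.0592175	0.00066354	0
1.0014467	8.86894e-05	0.0591756	0.000663285	0
1.022	8.29395e-05	0.0585883	0.00065972	4.48306e-21
1.0889373	6.72755e-05	0.0567748	0.000648709	1.45198e-07
1.17	5.30851e-05	0.0547601	0.000636469	1.56935e-06
1.1840715	5.10319e-05	0.0544286	0.000634453	2.06088e-06
1.25	4.26776e-05	0.0529403	0.000625398	5.73764e-06
1.287517	3.87103e-05	0.0521379	0.000674179	9.06158e-06
1.33	3.47784e-05	0.0512652	0.000732121	1.41442e-05
1.4	2.93637e-05	0.0499035	0.00083399	2.61456e-05
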