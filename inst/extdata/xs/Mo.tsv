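# Mass attenuation coefficients (cm^2/g) for Mo (Z=42, A=95.95), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	1614.37	0.168832	2.05139	0
0.010873643	1238.29	0.168291	1.80654	0
0.01182361	949.831	0.167708	1.59091	0
0.012856571	728.565	0.167081	1.40103	0
0.013979776	558.843	0.166405	1.2338	0
0.015	447.123	0.165798	1.10872	0
0.015201108	428.391	0.165679	1.08576	0
0.016529142	327.307	0.164899	0.951846	0
0.017973198	250.076	0.164062	0.834451	0
0.019543413	191.067	0.163164	0.731534	0
0.02	177.402	0.162905	0.70546	0
0.021250809	145.653	0.162202	0.637449	0
0.02310737	110.938	0.161174	0.554188	0
0.025126128	84.4966	0.160075	0.481803	0
0.027321253	64.3575	0.158903	0.418872	0
0.029708154	49.0183	0.157654	0.364161	0
0.03	47.4852	0.157503	0.35826	0
0.032303585	37.2495	0.156326	0.313997	0
0.035125763	28.2977	0.154915	0.270449	0
0.038194499	21.4972	0.15342	0.232941	0
0.04	18.4737	0.152559	0.214531	0
0.041531333	16.3208	0.151838	0.200119	0
0.045159687	12.3813	0.150168	0.171377	0
0.04910503	9.39271	0.148408	0.146764	0
0.05	8.84951	0.148017	0.141938	0
0.053395054	7.122	0.146557	0.125874	0
0.058059873	5.39951	0.144615	0.108003	0
0.06	4.84355	0.143829	0.101703	0
0.06313223	4.09211	0.142583	0.0924303	0
0.06864773	3.10055	0.140461	0.0789722	0
0.074645088	2.34925	0.138252	0.0674736	0
0.08	1.86744	0.13636	0.0592385	0
0.0811664	1.78035	0.135957	0.057547	0
0.088257442	1.35049	0.13358	0.0486652	0
0.095967988	1.02442	0.131125	0.0411542	0
0.1	0.894343	0.129891	0.0379001	0
0.10435216	0.777072	0.128597	0.0349123	0
0.11346881	0.589449	0.126	0.0297075	0
0.12338193	0.447127	0.123341	0.0252786	0
0.1341611	0.339169	0.120627	0.0215099	0
0.14588198	0.257277	0.117865	0.0183032	0
0.15	0.2347	0.116937	0.0173469	0
0.15862685	0.195158	0.115061	0.015504	0
0.17248517	0.148037	0.112224	0.0131033	0
0.1875542	0.112294	0.10936	0.0110743	0
0.2	0.0908431	0.107151	0.00973349	0
0.20393974	0.0851805	0.106479	0.00935543	0
0.22175678	0.0646138	0.103587	0.00789209	0
0.24113039	0.0490128	0.100691	0.00665765	0
0.26219657	0.0371788	0.097799	0.00561629	0
0.28510318	0.028202	0.0949168	0.00473782	0
0.3	0.0238397	0.0931716	0.00427226	0
0.310011	0.0213927	0.0920505	0.00399396	0
0.33709488	0.0162274	0.0892053	0.00336325	0
0.36654493	0.0123093	0.0863862	0.00283213	0
0.39856785	0.00933726	0.0835973	0.00238489	0
0.4	0.00922741	0.0834786	0.0023674	0
0.43338843	0.00708279	0.0808422	0.00229256	0
0.47125109	0.00537266	0.0781241	0.00221691	0
0.5	0.00441913	0.076226	0.00216493	0
0.511	0.00411296	0.0755336	0.00206638	0
0.51242159	0.00407543	0.0754454	0.00205413	0
0.55718892	0.00309143	0.0728084	0.00171693	0
0.6	0.00242152	0.0705139	0.0014653	0
0.60586731	0.002345	0.0702148	0.00145289	0
0.65879846	0.00177881	0.0676662	0.00135037	0
0.71635389	0.00134932	0.0651639	0.00125508	0
0.77893761	0.00102352	0.0627088	0.00116651	0
0.8	0.000937276	0.0619368	0.00113964	0
0.84698892	0.000776396	0.0603019	0.0011742	0
0.92098547	0.000588936	0.0579441	0.00122683	0
1	0.000448874	0.0556757	0.00128084	0
1.0014467	0.000446738	0.0556362	0.00128035	0
1.022	0.000417775	0.0550841	0.00127347	6.80872e-21
1.0889373	0.000338874	0.053379	0.00125222	2.20523e-07
1.17	0.000267395	0.0514849	0.00122859	2.38348e-06
1.1840715	0.000257053	0.0511732	0.0012247	3.13e-06
1.25	0.000214972	0.0497739	0.00120722	8.71414e-06
1.287517	0.000194988	0.0490195	0.00130138	1.37624e-05
1.33	0.000175183	0.048199	0.00141323	2.14817e-05
1.4	0.000147908	0.0469188	0.00160987	3.97091e-05
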