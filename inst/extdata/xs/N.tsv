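# Mass attenuation coefficients (cm^2/g) for N (Z=7, A=14.007), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	3.48354	0.192754	0.159356	0
0.010873643	2.67204	0.192137	0.140336	0
0.01182361	2.04958	0.191471	0.123586	0
0.012856571	1.57213	0.190755	0.108835	0
0.013979776	1.20589	0.189984	0.0958446	0
0.015	0.964819	0.18929	0.0861281	0
0.015201108	0.9244	0.189154	0.0843441	0
0.016529142	0.706277	0.188264	0.0739416	0
0.017973198	0.539623	0.187308	0.064822	0
0.019543413	0.412293	0.186283	0.0568272	0
0.02	0.382805	0.185987	0.0548017	0
0.021250809	0.314296	0.185185	0.0495185	0
0.02310737	0.239386	0.18401	0.0430506	0
0.025126128	0.18233	0.182756	0.0374275	0
0.027321253	0.138873	0.181418	0.0325389	0
0.029708154	0.105774	0.179992	0.0282888	0
0.03	0.102465	0.17982	0.0278304	0
0.032303585	0.0803785	0.178476	0.024392	0
0.035125763	0.0610619	0.176865	0.0210091	0
0.038194499	0.0463874	0.175159	0.0180954	0
0.04	0.0398633	0.174175	0.0166652	0
0.041531333	0.0352176	0.173353	0.0155457	0
0.045159687	0.0267168	0.171446	0.013313	0
0.04910503	0.020268	0.169436	0.011401	0
0.05	0.0190958	0.168989	0.0110261	0
0.053395054	0.0153681	0.167323	0.00977821	0
0.058059873	0.0116513	0.165106	0.00838988	0
0.06	0.0104516	0.164208	0.00790054	0
0.06313223	0.00883013	0.162786	0.00718019	0
0.06864773	0.00669049	0.160363	0.00613474	0
0.074645088	0.00506931	0.157841	0.0052415	0
0.08	0.00402964	0.15568	0.00460178	0
0.0811664	0.00384172	0.155221	0.00447038	0
0.088257442	0.00291414	0.152507	0.00378042	0
0.095967988	0.00221052	0.149704	0.00319695	0
0.1	0.00192985	0.148296	0.00294417	0
0.10435216	0.0016768	0.146818	0.00271207	0
0.11346881	0.00127194	0.143853	0.00230774	0
0.12338193	0.000964828	0.140818	0.0019637	0
0.1341611	0.000731872	0.137719	0.00167094	0
0.14588198	0.000555162	0.134565	0.00142183	0
0.15	0.000506444	0.133506	0.00134755	0
0.15862685	0.000421119	0.131364	0.00120438	0
0.17248517	0.00031944	0.128125	0.00101789	0
0.1875542	0.000242312	0.124856	0.000860275	0
0.2	0.000196025	0.122334	0.000756119	0
0.20393974	0.000183806	0.121566	0.00072675	0
0.22175678	0.000139426	0.118264	0.000613076	0
0.24113039	0.000105762	0.114958	0.000517181	0
0.26219657	8.02258e-05	0.111656	0.000436286	0
0.28510318	6.08554e-05	0.108366	0.000368044	0
0.3	5.14422e-05	0.106373	0.000331879	0
0.310011	4.61619e-05	0.105093	0.00031026	0
0.33709488	3.50162e-05	0.101845	0.000261264	0
0.36654493	2.65616e-05	0.0986264	0.000220006	0
0.39856785	2.01483e-05	0.0954423	0.000185264	0
0.4	1.99113e-05	0.0953068	0.000183905	0
0.43338843	1.52835e-05	0.0922969	0.000178092	0
0.47125109	1.15933e-05	0.0891935	0.000172214	0
0.5	9.53577e-06	0.0870265	0.000168176	0
0.511	8.87511e-06	0.086236	0.000160521	0
0.51242159	8.79413e-06	0.0861353	0.000159569	0
0.55718892	6.6708e-06	0.0831247	0.000133375	0
0.6	5.22525e-06	0.0805051	0.000113828	0
0.60586731	5.06014e-06	0.0801636	0.000112864	0
0.65879846	3.83838e-06	0.0772539	0.0001049	0
0.71635389	2.91161e-06	0.074397	9.74974e-05	0
0.77893761	2.2086e-06	0.071594	9.06174e-05	0
0.8	2.02249e-06	0.0707127	8.85294e-05	0
0.84698892	1.67534e-06	0.0688462	9.12144e-05	0
0.92098547	1.27083e-06	0.0661543	9.53026e-05	0
1	9.68598e-07	0.0635644	9.94988e-05	0
1.0014467	9.63989e-07	0.0635194	9.94606e-05	0
1.022	9.01491e-07	0.062889	9.8926e-05	1.29558e-21
1.0889373	7.31235e-07	0.0609423	9.72749e-05	4.19615e-08
1.17	5.76996e-07	0.0587798	9.54394e-05	4.53533e-07
1.1840715	5.54679e-07	0.058424	9.51372e-05	5.95583e-07
1.25	4.63875e-07	0.0568264	9.37794e-05	1.65814e-06
1.287517	4.20753e-07	0.0559652	0.000101094	2.61874e-06
1.33	3.78016e-07	0.0550283	0.000109783	4.08758e-06
1.4	3.19162e-07	0.0535667	0.000125058	7.55593e-06
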