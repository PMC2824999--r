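# Mass attenuation coefficients (cm^2/g) for C (Z=6, A=12.011), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	2.03014	0.192674	0.126406	0
0.010873643	1.55722	0.192057	0.111319	0
0.01182361	1.19446	0.191392	0.0980319	0
0.012856571	0.916205	0.190675	0.0863311	0
0.013979776	0.702772	0.189905	0.0760268	0
0.015	0.562278	0.189212	0.0683193	0
0.015201108	0.538723	0.189076	0.0669042	0
0.016529142	0.411605	0.188185	0.0586526	0
0.017973198	0.314482	0.18723	0.0514188	0
0.019543413	0.240276	0.186205	0.0450771	0
0.02	0.223091	0.18591	0.0434704	0
0.021250809	0.183166	0.185108	0.0392795	0
0.02310737	0.13951	0.183934	0.034149	0
0.025126128	0.106259	0.18268	0.0296886	0
0.027321253	0.0809326	0.181342	0.0258108	0
0.029708154	0.0616429	0.179917	0.0224395	0
0.03	0.0597149	0.179745	0.0220759	0
0.032303585	0.0468431	0.178401	0.0193485	0
0.035125763	0.0355857	0.176792	0.0166651	0
0.038194499	0.0270337	0.175086	0.0143538	0
0.04	0.0232316	0.174103	0.0132194	0
0.041531333	0.0205241	0.17328	0.0123313	0
0.045159687	0.0155701	0.171374	0.0105603	0
0.04910503	0.0118118	0.169366	0.00904359	0
0.05	0.0111287	0.168919	0.00874623	0
0.053395054	0.00895626	0.167253	0.00775636	0
0.058059873	0.00679014	0.165037	0.0066551	0
0.06	0.006091	0.16414	0.00626694	0
0.06313223	0.00514603	0.162718	0.00569554	0
0.06864773	0.00389909	0.160297	0.00486626	0
0.074645088	0.0029543	0.157775	0.00415771	0
0.08	0.0023484	0.155616	0.00365027	0
0.0811664	0.00223888	0.155156	0.00354604	0
0.088257442	0.00169831	0.152444	0.00299874	0
0.095967988	0.00128825	0.149642	0.00253592	0
0.1	0.00112468	0.148234	0.0023354	0
0.10435216	0.000977205	0.146756	0.00215129	0
0.11346881	0.00074126	0.143793	0.00183057	0
0.12338193	0.000562284	0.140759	0.00155766	0
0.1341611	0.000426521	0.137662	0.00132544	0
0.14588198	0.000323538	0.134509	0.00112784	0
0.15	0.000295146	0.13345	0.00106892	0
0.15862685	0.00024542	0.131309	0.000955352	0
0.17248517	0.000186164	0.128071	0.000807421	0
0.1875542	0.000141215	0.124804	0.000682395	0
0.2	0.00011424	0.122283	0.000599776	0
0.20393974	0.000107119	0.121515	0.00057648	0
0.22175678	8.12549e-05	0.118215	0.00048631	0
0.24113039	6.1636e-05	0.11491	0.000410243	0
0.26219657	4.67541e-05	0.11161	0.000346075	0
0.28510318	3.54654e-05	0.108321	0.000291944	0
0.3	2.99795e-05	0.106329	0.000263256	0
0.310011	2.69023e-05	0.105049	0.000246107	0
0.33709488	2.04068e-05	0.101803	0.000207243	0
0.36654493	1.54796e-05	0.0985853	0.000174516	0
0.39856785	1.1742e-05	0.0954026	0.000146957	0
0.4	1.16039e-05	0.0952671	0.000145879	0
0.43338843	8.90694e-06	0.0922584	0.000141268	0
0.47125109	6.75637e-06	0.0891564	0.000136605	0
0.5	5.55727e-06	0.0869903	0.000133402	0
0.511	5.17225e-06	0.0862001	0.00012733	0
0.51242159	5.12506e-06	0.0860994	0.000126575	0
0.55718892	3.88762e-06	0.0830901	0.000105797	0
0.6	3.04518e-06	0.0804715	9.02915e-05	0
0.60586731	2.94896e-06	0.0801303	8.95271e-05	0
0.65879846	2.23693e-06	0.0772218	8.32096e-05	0
0.71635389	1.69683e-06	0.074366	7.73378e-05	0
0.77893761	1.28713e-06	0.0715642	7.18804e-05	0
0.8	1.17867e-06	0.0706832	7.02242e-05	0
0.84698892	9.76355e-07	0.0688175	7.2354e-05	0
0.92098547	7.40615e-07	0.0661268	7.55969e-05	0
1	5.64481e-07	0.0635379	7.89254e-05	0
1.0014467	5.61795e-07	0.063493	7.88951e-05	0
1.022	5.25372e-07	0.0628628	7.8471e-05	1.11003e-21
1.0889373	4.2615e-07	0.060917	7.71613e-05	3.5952e-08
1.17	3.36262e-07	0.0587553	7.57054e-05	3.88581e-07
1.1840715	3.23257e-07	0.0583997	7.54657e-05	5.10287e-07
1.25	2.70337e-07	0.0568028	7.43886e-05	1.42067e-06
1.287517	2.45207e-07	0.0559419	8.01909e-05	2.2437e-06
1.33	2.203e-07	0.0550054	8.70829e-05	3.50218e-06
1.4	1.86002e-07	0.0535444	9.91998e-05	6.47381e-06
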