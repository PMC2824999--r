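# Mass attenuation coefficients (cm^2/g) for Mg (Z=12, A=24.305), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	22.701	0.19043	0.353368	0
0.010873643	17.4127	0.18982	0.311191	0
0.01182361	13.3564	0.189163	0.274048	0
0.012856571	10.245	0.188455	0.241338	0
0.013979776	7.85838	0.187693	0.212532	0
0.015	6.28738	0.187008	0.190986	0
0.015201108	6.02399	0.186874	0.18703	0
0.016529142	4.60256	0.185994	0.163963	0
0.017973198	3.51653	0.18505	0.143741	0
0.019543413	2.68676	0.184037	0.126013	0
0.02	2.4946	0.183745	0.121521	0
0.021250809	2.04816	0.182952	0.109806	0
0.02310737	1.55999	0.181792	0.0954633	0
0.025126128	1.18818	0.180553	0.0829944	0
0.027321253	0.904987	0.179231	0.072154	0
0.029708154	0.68929	0.177822	0.0627296	0
0.03	0.66773	0.177652	0.0617131	0
0.032303585	0.523798	0.176324	0.0540886	0
0.035125763	0.397918	0.174733	0.0465871	0
0.038194499	0.30229	0.173047	0.0401259	0
0.04	0.259775	0.172075	0.0369546	0
0.041531333	0.2295	0.171263	0.034472	0
0.045159687	0.174104	0.169379	0.0295211	0
0.04910503	0.132079	0.167394	0.0252813	0
0.05	0.124441	0.166952	0.02445	0
0.053395054	0.100149	0.165306	0.0216829	0
0.058059873	0.0759272	0.163116	0.0186043	0
0.06	0.0681094	0.162228	0.0175192	0
0.06313223	0.0575428	0.160824	0.0159219	0
0.06864773	0.0435996	0.15843	0.0136036	0
0.074645088	0.0330349	0.155938	0.0116229	0
0.08	0.0262597	0.153804	0.0102043	0
0.0811664	0.0250351	0.15335	0.00991292	0
0.088257442	0.0189904	0.150669	0.00838296	0
0.095967988	0.0144052	0.1479	0.00708914	0
0.1	0.0125761	0.146508	0.0065286	0
0.10435216	0.0109271	0.145048	0.00601393	0
0.11346881	0.00828875	0.142119	0.00511735	0
0.12338193	0.00628744	0.13912	0.00435443	0
0.1341611	0.00476935	0.136059	0.00370526	0
0.14588198	0.00361779	0.132943	0.00315286	0
0.15	0.00330032	0.131897	0.00298815	0
0.15862685	0.00274428	0.12978	0.00267068	0
0.17248517	0.00208168	0.12658	0.00225714	0
0.1875542	0.00157906	0.123351	0.00190763	0
0.2	0.00127742	0.120859	0.00167667	0
0.20393974	0.0011978	0.1201	0.00161155	0
0.22175678	0.00090859	0.116838	0.00135948	0
0.24113039	0.000689212	0.113572	0.00114683	0
0.26219657	0.000522803	0.11031	0.000967451	0
0.28510318	0.000396573	0.107059	0.000816126	0
0.3	0.00033523	0.105091	0.000735931	0
0.310011	0.000300821	0.103826	0.000687991	0
0.33709488	0.000228188	0.100617	0.000579346	0
0.36654493	0.000173092	0.0974374	0.000487857	0
0.39856785	0.000131299	0.0942917	0.000410816	0
0.4	0.000129755	0.0941579	0.000407804	0
0.43338843	9.95972e-05	0.0911842	0.000394912	0
0.47125109	7.55496e-05	0.0881183	0.00038188	0
0.5	6.21412e-05	0.0859774	0.000372926	0
0.511	5.78359e-05	0.0851964	0.00035595	0
0.51242159	5.73082e-05	0.0850969	0.000353839	0
0.55718892	4.34712e-05	0.0821226	0.000295755	0
0.6	3.40511e-05	0.0795346	0.000252409	0
0.60586731	3.29752e-05	0.0791972	0.000250272	0
0.65879846	2.50133e-05	0.0763226	0.000232612	0
0.71635389	1.89739e-05	0.0735001	0.000216197	0
0.77893761	1.43927e-05	0.070731	0.000200941	0
0.8	1.31799e-05	0.0698602	0.000196311	0
0.84698892	1.09176e-05	0.0680162	0.000202265	0
0.92098547	8.28154e-06	0.0653568	0.000211331	0
1	6.31201e-06	0.0627981	0.000220635	0
1.0014467	6.28197e-06	0.0627537	0.000220551	0
1.022	5.8747e-06	0.0621308	0.000219365	2.19421e-21
1.0889373	4.7652e-06	0.0602077	0.000215704	7.10668e-08
1.17	3.76008e-06	0.0580712	0.000211634	7.68112e-07
1.1840715	3.61465e-06	0.0577197	0.000210964	1.00869e-06
1.25	3.02291e-06	0.0561414	0.000207953	2.80826e-06
1.287517	2.7419e-06	0.0552905	0.000224173	4.43515e-06
1.33	2.46339e-06	0.054365	0.00024344	6.9228e-06
1.4	2.07987e-06	0.052921	0.000277312	1.27969e-05
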