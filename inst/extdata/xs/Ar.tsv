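# Mass attenuation coefficients (cm^2/g) for Ar (Z=18, A=39.948), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	85.636	0.173791	0.592455	0
0.010873643	65.6869	0.173235	0.521741	0
0.01182361	50.3849	0.172635	0.459467	0
0.012856571	38.6476	0.171989	0.404626	0
0.013979776	29.6445	0.171293	0.356331	0
0.015	23.7182	0.170668	0.320207	0
0.015201108	22.7245	0.170546	0.313575	0
0.016529142	17.3624	0.169743	0.2749	0
0.017973198	13.2656	0.168881	0.240995	0
0.019543413	10.1354	0.167956	0.211272	0
0.02	9.4105	0.16769	0.203742	0
0.021250809	7.72635	0.166967	0.1841	0
0.02310737	5.88483	0.165908	0.160054	0
0.025126128	4.48223	0.164777	0.139148	0
0.027321253	3.41392	0.16357	0.120973	0
0.029708154	2.60024	0.162285	0.105172	0
0.03	2.51891	0.162129	0.103468	0
0.032303585	1.97595	0.160918	0.0906847	0
0.035125763	1.50109	0.159466	0.0781077	0
0.038194499	1.14034	0.157927	0.067275	0
0.04	0.979961	0.15704	0.061958	0
0.041531333	0.865754	0.156299	0.0577957	0
0.045159687	0.65678	0.154579	0.049495	0
0.04910503	0.498248	0.152767	0.0423865	0
0.05	0.469433	0.152364	0.0409928	0
0.053395054	0.377795	0.150862	0.0363534	0
0.058059873	0.286424	0.148863	0.0311919	0
0.06	0.256932	0.148053	0.0293726	0
0.06313223	0.217071	0.146771	0.0266945	0
0.06864773	0.164473	0.144587	0.0228077	0
0.074645088	0.124619	0.142313	0.0194869	0
0.08	0.0990608	0.140365	0.0171085	0
0.0811664	0.094441	0.139951	0.01662	0
0.088257442	0.0716384	0.137504	0.0140549	0
0.095967988	0.0543414	0.134977	0.0118856	0
0.1	0.0474415	0.133707	0.0109458	0
0.10435216	0.0412207	0.132374	0.0100829	0
0.11346881	0.031268	0.129701	0.00857973	0
0.12338193	0.0237184	0.126964	0.00730063	0
0.1341611	0.0179916	0.124171	0.00621222	0
0.14588198	0.0136476	0.121327	0.00528608	0
0.15	0.0124499	0.120372	0.00500992	0
0.15862685	0.0103524	0.118441	0.00447766	0
0.17248517	0.0078528	0.11552	0.00378431	0
0.1875542	0.00595675	0.112573	0.00319833	0
0.2	0.00481888	0.110299	0.0028111	0
0.20393974	0.0045185	0.109607	0.00270191	0
0.22175678	0.00342752	0.106629	0.00227929	0
0.24113039	0.00259995	0.103649	0.00192278	0
0.26219657	0.00197219	0.100672	0.00162202	0
0.28510318	0.00149601	0.0977049	0.00136832	0
0.3	0.0012646	0.0959084	0.00123386	0
0.310011	0.0011348	0.0947543	0.00115348	0
0.33709488	0.000860803	0.0918257	0.000971329	0
0.36654493	0.000652963	0.0889237	0.00081794	0
0.39856785	0.000495306	0.0860529	0.000688773	0
0.4	0.000489479	0.0859307	0.000683722	0
0.43338843	0.000375715	0.0832169	0.000662109	0
0.47125109	0.000284999	0.0804189	0.000640258	0
0.5	0.000234418	0.078465	0.000625246	0
0.511	0.000218177	0.0777523	0.000596785	0
0.51242159	0.000216186	0.0776615	0.000593246	0
0.55718892	0.000163988	0.074947	0.000495862	0
0.6	0.000128452	0.0725851	0.000423189	0
0.60586731	0.000124394	0.0722773	0.000419606	0
0.65879846	9.43589e-05	0.0696539	0.000389996	0
0.71635389	7.15761e-05	0.067078	0.000362476	0
0.77893761	5.42941e-05	0.0645508	0.000336898	0
0.8	4.97189e-05	0.0637561	0.000329135	0
0.84698892	4.11849e-05	0.0620732	0.000339117	0
0.92098547	3.12408e-05	0.0596462	0.000354316	0
1	2.38111e-05	0.0573111	0.000369917	0
1.0014467	2.36978e-05	0.0572705	0.000369775	0
1.022	2.21614e-05	0.0567021	0.000367787	3.00374e-21
1.0889373	1.7976e-05	0.054947	0.000361649	9.72858e-08
1.17	1.41843e-05	0.0529972	0.000354825	1.0515e-06
1.1840715	1.36357e-05	0.0526763	0.000353701	1.38083e-06
1.25	1.14034e-05	0.051236	0.000348653	3.84433e-06
1.287517	1.03434e-05	0.0504594	0.000375848	6.07144e-06
1.33	9.29277e-06	0.0496148	0.00040815	9.47688e-06
1.4	7.84598e-06	0.0482969	0.000464941	1.75181e-05
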