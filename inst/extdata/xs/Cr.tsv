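# Mass attenuation coefficients (cm^2/g) for Cr (Z=24, A=51.996), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	240.108	0.178029	0.934388	0
0.010873643	184.174	0.177459	0.822862	0
0.01182361	141.27	0.176845	0.724647	0
0.012856571	108.361	0.176183	0.638155	0
0.013979776	83.1178	0.175471	0.561986	0
0.015	66.5013	0.17483	0.505013	0
0.015201108	63.7154	0.174705	0.494553	0
0.016529142	48.681	0.173882	0.433558	0
0.017973198	37.1942	0.172999	0.380085	0
0.019543413	28.4178	0.172052	0.333207	0
0.02	26.3853	0.17178	0.321331	0
0.021250809	21.6633	0.171038	0.290352	0
0.02310737	16.5	0.169954	0.252428	0
0.025126128	12.5673	0.168795	0.219457	0
0.027321253	9.572	0.167559	0.190792	0
0.029708154	7.29059	0.166242	0.165872	0
0.03	7.06255	0.166083	0.163184	0
0.032303585	5.54019	0.164842	0.143023	0
0.035125763	4.20877	0.163355	0.123187	0
0.038194499	3.19731	0.161778	0.106103	0
0.04	2.74763	0.16087	0.0977169	0
0.041531333	2.42741	0.16011	0.0911522	0
0.045159687	1.84149	0.158349	0.0780609	0
0.04910503	1.397	0.156493	0.0668498	0
0.05	1.3162	0.15608	0.0646517	0
0.053395054	1.05927	0.154541	0.0573347	0
0.058059873	0.803079	0.152494	0.0491942	0
0.06	0.72039	0.151664	0.0463249	0
0.06313223	0.608628	0.150351	0.0421012	0
0.06864773	0.461151	0.148113	0.0359711	0
0.074645088	0.349409	0.145783	0.0307336	0
0.08	0.277748	0.143788	0.0269826	0
0.0811664	0.264795	0.143363	0.0262121	0
0.088257442	0.200861	0.140857	0.0221666	0
0.095967988	0.152363	0.138268	0.0187454	0
0.1	0.133017	0.136967	0.0172632	0
0.10435216	0.115575	0.135602	0.0159023	0
0.11346881	0.0876697	0.132864	0.0135315	0
0.12338193	0.066502	0.130061	0.0115142	0
0.1341611	0.0504452	0.127199	0.00979758	0
0.14588198	0.0382652	0.124286	0.00833692	0
0.15	0.0349073	0.123307	0.00790138	0
0.15862685	0.0290261	0.121329	0.00706192	0
0.17248517	0.0220178	0.118337	0.00596842	0
0.1875542	0.0167016	0.115318	0.00504424	0
0.2	0.0135113	0.112988	0.00443352	0
0.20393974	0.012669	0.112279	0.00426131	0
0.22175678	0.00961012	0.10923	0.00359478	0
0.24113039	0.00728977	0.106176	0.0030325	0
0.26219657	0.00552966	0.103127	0.00255817	0
0.28510318	0.00419453	0.100088	0.00215803	0
0.3	0.00354572	0.0982473	0.00194598	0
0.310011	0.00318177	0.0970651	0.00181921	0
0.33709488	0.00241353	0.094065	0.00153193	0
0.36654493	0.00183079	0.0910923	0.00129001	0
0.39856785	0.00138875	0.0881514	0.0010863	0
0.4	0.00137241	0.0880263	0.00107833	0
0.43338843	0.00105344	0.0852463	0.00104424	0
0.47125109	0.000799085	0.08238	0.00100978	0
0.5	0.000657265	0.0803785	0.000986105	0
0.511	0.000611728	0.0796484	0.000941217	0
0.51242159	0.000606147	0.0795554	0.000935636	0
0.55718892	0.000459793	0.0767747	0.000782047	0
0.6	0.000360157	0.0743552	0.000667431	0
0.60586731	0.000348777	0.0740399	0.00066178	0
0.65879846	0.000264565	0.0713525	0.000615081	0
0.71635389	0.000200686	0.0687138	0.000571678	0
0.77893761	0.000152231	0.0661249	0.000531337	0
0.8	0.000139403	0.0653109	0.000519094	0
0.84698892	0.000115475	0.063587	0.000534837	0
0.92098547	8.75935e-05	0.0611007	0.000558809	0
1	6.67618e-05	0.0587087	0.000583413	0
1.0014467	6.64442e-05	0.0586671	0.000583189	0
1.022	6.21364e-05	0.0580849	0.000580054	4.10265e-21
1.0889373	5.04013e-05	0.0562869	0.000570373	1.32878e-07
1.17	3.97701e-05	0.0542896	0.000559611	1.43618e-06
1.1840715	3.8232e-05	0.0539609	0.000557839	1.88601e-06
1.25	3.19731e-05	0.0524854	0.000549877	5.25077e-06
1.287517	2.90009e-05	0.05169	0.000592767	8.29266e-06
1.33	2.60552e-05	0.0508247	0.000643713	1.2944e-05
1.4	2.19987e-05	0.0494747	0.00073328	2.39271e-05
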