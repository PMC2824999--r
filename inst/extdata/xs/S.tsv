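# Mass attenuation coefficients (cm^2/g) for S (Z=16, A=32.06), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	62.8061	0.192489	0.549928	0
0.010873643	48.1752	0.191873	0.48429	0
0.01182361	36.9527	0.191208	0.426486	0
0.012856571	28.3444	0.190493	0.375582	0
0.013979776	21.7415	0.189723	0.330753	0
0.015	17.3951	0.189031	0.297222	0
0.015201108	16.6663	0.188895	0.291066	0
0.016529142	12.7337	0.188005	0.255167	0
0.017973198	9.72906	0.187051	0.223696	0
0.019543413	7.43337	0.186027	0.196107	0
0.02	6.90173	0.185732	0.189117	0
0.021250809	5.66656	0.184931	0.170885	0
0.02310737	4.31598	0.183758	0.148565	0
0.025126128	3.2873	0.182505	0.12916	0
0.027321253	2.50379	0.181169	0.11229	0
0.029708154	1.90703	0.179745	0.0976228	0
0.03	1.84739	0.179573	0.096041	0
0.032303585	1.44917	0.178231	0.0841752	0
0.035125763	1.10091	0.176623	0.072501	0
0.038194499	0.836336	0.174918	0.0624459	0
0.04	0.71871	0.173936	0.0575106	0
0.041531333	0.63495	0.173115	0.053647	0
0.045159687	0.481687	0.17121	0.0459422	0
0.04910503	0.365419	0.169204	0.039344	0
0.05	0.344286	0.168757	0.0380503	0
0.053395054	0.277078	0.167093	0.0337439	0
0.058059873	0.210065	0.16488	0.0289529	0
0.06	0.188436	0.163983	0.0272642	0
0.06313223	0.159202	0.162563	0.0247784	0
0.06864773	0.120625	0.160143	0.0211706	0
0.074645088	0.0913965	0.157624	0.0180881	0
0.08	0.0726519	0.155467	0.0158804	0
0.0811664	0.0692637	0.155008	0.015427	0
0.088257442	0.0525401	0.152298	0.013046	0
0.095967988	0.0398544	0.149499	0.0110325	0
0.1	0.034794	0.148092	0.0101601	0
0.10435216	0.0302316	0.146616	0.00935916	0
0.11346881	0.0229322	0.143656	0.00796386	0
0.12338193	0.0173952	0.140625	0.00677658	0
0.1341611	0.0131952	0.13753	0.0057663	0
0.14588198	0.0100092	0.13438	0.00490664	0
0.15	0.00913087	0.133323	0.0046503	0
0.15862685	0.0075925	0.131184	0.00415624	0
0.17248517	0.0057593	0.127949	0.00351267	0
0.1875542	0.00436873	0.124684	0.00296875	0
0.2	0.0035342	0.122166	0.00260932	0
0.20393974	0.0033139	0.121399	0.00250797	0
0.22175678	0.00251376	0.118102	0.00211568	0
0.24113039	0.00190682	0.1148	0.00178476	0
0.26219657	0.00144642	0.111503	0.00150559	0
0.28510318	0.00109718	0.108217	0.0012701	0
0.3	0.00092747	0.106227	0.00114529	0
0.310011	0.00083227	0.104949	0.00107069	0
0.33709488	0.000631319	0.101705	0.000901606	0
0.36654493	0.000478888	0.098491	0.000759227	0
0.39856785	0.000363261	0.0953113	0.000639332	0
0.4	0.000358987	0.095176	0.000634644	0
0.43338843	0.000275552	0.0921702	0.000614582	0
0.47125109	0.00020902	0.0890711	0.0005943	0
0.5	0.000171924	0.0869071	0.000580365	0
0.511	0.000160013	0.0861176	0.000553947	0
0.51242159	0.000158553	0.0860171	0.000550662	0
0.55718892	0.00012027	0.0830106	0.000460268	0
0.6	9.42079e-05	0.0803946	0.000392812	0
0.60586731	9.12312e-05	0.0800536	0.000389486	0
0.65879846	6.92035e-05	0.0771479	0.000362002	0
0.71635389	5.24944e-05	0.0742949	0.000336457	0
0.77893761	3.98197e-05	0.0714958	0.000312715	0
0.8	3.64642e-05	0.0706156	0.000305509	0
0.84698892	3.02053e-05	0.0687517	0.000314775	0
0.92098547	2.29122e-05	0.0660635	0.000328883	0
1	1.74632e-05	0.0634772	0.000343364	0
1.0014467	1.73801e-05	0.0634322	0.000343232	0
1.022	1.62533e-05	0.0628027	0.000341387	2.95725e-21
1.0889373	1.31837e-05	0.0608587	0.000335689	9.57803e-08
1.17	1.04029e-05	0.0586991	0.000329355	1.03522e-06
1.1840715	1.00005e-05	0.0583438	0.000328312	1.35946e-06
1.25	8.36337e-06	0.0567485	0.000323626	3.78484e-06
1.287517	7.5859e-06	0.0558884	0.000348869	5.97748e-06
1.33	6.81539e-06	0.0549528	0.000378853	9.33021e-06
1.4	5.7543e-06	0.0534932	0.000431567	1.7247e-05
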