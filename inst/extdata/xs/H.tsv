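# Mass attenuation coefficients (cm^2/g) for H (Z=1, A=1.008), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	0.00762017	0.382639	0.0170808	0
0.010873643	0.00584503	0.381414	0.0150421	0
0.01182361	0.00448341	0.380093	0.0132467	0
0.012856571	0.00343899	0.378671	0.0116656	0
0.013979776	0.00263787	0.37714	0.0102732	0
0.015	0.00211052	0.375764	0.00923175	0
0.015201108	0.0020221	0.375494	0.00904054	0
0.016529142	0.00154496	0.373726	0.00792553	0
0.017973198	0.00118041	0.371828	0.00694804	0
0.019543413	0.000901881	0.369793	0.0060911	0
0.02	0.000837377	0.369207	0.005874	0
0.021250809	0.000687516	0.367614	0.0053077	0
0.02310737	0.000523651	0.365283	0.00461444	0
0.025126128	0.000398843	0.362792	0.00401172	0
0.027321253	0.000303782	0.360136	0.00348773	0
0.029708154	0.000231378	0.357306	0.00303218	0
0.03	0.000224141	0.356964	0.00298304	0
0.032303585	0.000175826	0.354295	0.00261449	0
0.035125763	0.000133571	0.351099	0.00225189	0
0.038194499	0.000101471	0.347711	0.00193958	0
0.04	8.72001e-05	0.345758	0.00178629	0
0.041531333	7.70376e-05	0.344126	0.00166628	0
0.045159687	5.84424e-05	0.34034	0.00142697	0
0.04910503	4.43357e-05	0.336351	0.00122203	0
0.05	4.17717e-05	0.335464	0.00118185	0
0.053395054	3.36175e-05	0.332156	0.00104809	0
0.058059873	2.54869e-05	0.327755	0.00089928	0
0.06	2.28626e-05	0.325972	0.00084683	0
0.06313223	1.93157e-05	0.323149	0.000769619	0
0.06864773	1.46353e-05	0.318341	0.00065756	0
0.074645088	1.1089e-05	0.313333	0.000561817	0
0.08	8.81475e-06	0.309044	0.000493248	0
0.0811664	8.40367e-06	0.308132	0.000479163	0
0.088257442	6.37461e-06	0.302745	0.000405209	0
0.095967988	4.83547e-06	0.297181	0.00034267	0
0.1	4.2215e-06	0.294385	0.000315574	0
0.10435216	3.66795e-06	0.29145	0.000290697	0
0.11346881	2.78233e-06	0.285565	0.000247358	0
0.12338193	2.11054e-06	0.27954	0.000210481	0
0.1341611	1.60095e-06	0.273389	0.000179102	0
0.14588198	1.2144e-06	0.267128	0.000152401	0
0.15	1.10783e-06	0.265025	0.000144439	0
0.15862685	9.21188e-07	0.260773	0.000129093	0
0.17248517	6.98768e-07	0.254343	0.000109104	0
0.1875542	5.30051e-07	0.247853	9.22097e-05	0
0.2	4.288e-07	0.242847	8.10456e-05	0
0.20393974	4.02071e-07	0.241323	7.78977e-05	0
0.22175678	3.04991e-07	0.234768	6.57133e-05	0
0.24113039	2.31352e-07	0.228206	5.54348e-05	0
0.26219657	1.75492e-07	0.221651	4.67639e-05	0
0.28510318	1.3312e-07	0.215119	3.94493e-05	0
0.3	1.12529e-07	0.211163	3.55729e-05	0
0.310011	1.00978e-07	0.208623	3.32556e-05	0
0.33709488	7.65971e-08	0.202174	2.8004e-05	0
0.36654493	5.81028e-08	0.195785	2.35817e-05	0
0.39856785	4.40739e-08	0.189464	1.98577e-05	0
0.4	4.35554e-08	0.189195	1.97121e-05	0
0.43338843	3.34323e-08	0.18322	1.9089e-05	0
0.47125109	2.53601e-08	0.17706	1.8459e-05	0
0.5	2.08593e-08	0.172758	1.80262e-05	0
0.511	1.94141e-08	0.171189	1.72057e-05	0
0.51242159	1.9237e-08	0.170989	1.71036e-05	0
0.55718892	1.45922e-08	0.165012	1.4296e-05	0
0.6	1.14301e-08	0.159812	1.22008e-05	0
0.60586731	1.10689e-08	0.159134	1.20975e-05	0
0.65879846	8.39636e-09	0.153358	1.12438e-05	0
0.71635389	6.36907e-09	0.147687	1.04504e-05	0
0.77893761	4.83127e-09	0.142123	9.71295e-06	0
0.8	4.42415e-09	0.140373	9.48915e-06	0
0.84698892	3.66476e-09	0.136668	9.77694e-06	0
0.92098547	2.77991e-09	0.131324	1.02151e-05	0
1	2.11879e-09	0.126183	1.06649e-05	0
1.0014467	2.1087e-09	0.126094	1.06608e-05	0
1.022	1.97199e-09	0.124842	1.06035e-05	3.6741e-22
1.0889373	1.59956e-09	0.120978	1.04265e-05	1.18998e-08
1.17	1.26216e-09	0.116685	1.02298e-05	1.28617e-07
1.1840715	1.21335e-09	0.115979	1.01974e-05	1.689e-07
1.25	1.01472e-09	0.112807	1.00519e-05	4.7023e-07
1.287517	9.20387e-10	0.111098	1.08359e-05	7.42644e-07
1.33	8.26901e-10	0.109238	1.17672e-05	1.15919e-06
1.4	6.9816e-10	0.106336	1.34045e-05	2.14277e-06
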