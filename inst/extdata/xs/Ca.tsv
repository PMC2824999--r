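# Mass attenuation coefficients (cm^2/g) for Ca (Z=20, A=40.078), 0.010-1.40 MeV.
# Derived tables: incoherent = Klein-Nishina (free electrons) x Z/A;
# photoelectric/coherent partitioned from Hubbell & Seltzer (1995) water/air
# reference data with Z power laws (4.5 / 2.5); pair = near-threshold Z^2 form.
# Generated once by tools/make_coefficients.R; do not edit by hand.
energy_mev	photoelectric	incoherent	coherent	pair
0.01	137.137	0.192475	0.76849	0
0.010873643	105.19	0.191858	0.676765	0
0.01182361	80.686	0.191194	0.595988	0
0.012856571	61.89	0.190479	0.524852	0
0.013979776	47.4725	0.189709	0.462207	0
0.015	37.9821	0.189016	0.415349	0
0.015201108	36.3909	0.188881	0.406746	0
0.016529142	27.804	0.187991	0.356581	0
0.017973198	21.2434	0.187037	0.312602	0
0.019543413	16.2307	0.186013	0.274047	0
0.02	15.0699	0.185718	0.264279	0
0.021250809	12.3729	0.184917	0.238801	0
0.02310737	9.42392	0.183744	0.20761	0
0.025126128	7.1778	0.182492	0.180493	0
0.027321253	5.46703	0.181155	0.156918	0
0.029708154	4.164	0.179731	0.136422	0
0.03	4.03376	0.179559	0.134211	0
0.032303585	3.16426	0.178217	0.11763	0
0.035125763	2.40383	0.176609	0.101316	0
0.038194499	1.82614	0.174905	0.0872643	0
0.04	1.5693	0.173923	0.0803675	0
0.041531333	1.38641	0.173102	0.0749684	0
0.045159687	1.05176	0.171198	0.0642014	0
0.04910503	0.79789	0.169191	0.0549808	0
0.05	0.751747	0.168745	0.0531729	0
0.053395054	0.604999	0.167081	0.047155	0
0.058059873	0.458676	0.164867	0.0404599	0
0.06	0.411449	0.16397	0.0381001	0
0.06313223	0.347616	0.16255	0.0346262	0
0.06864773	0.263385	0.160131	0.0295845	0
0.074645088	0.199564	0.157612	0.025277	0
0.08	0.158635	0.155455	0.0221919	0
0.0811664	0.151237	0.154996	0.0215582	0
0.088257442	0.114721	0.152286	0.0182309	0
0.095967988	0.0870218	0.149488	0.0154172	0
0.1	0.0759725	0.148081	0.0141981	0
0.10435216	0.0660105	0.146605	0.0130788	0
0.11346881	0.0500724	0.143645	0.011129	0
0.12338193	0.0379824	0.140614	0.00946985	0
0.1341611	0.0288116	0.13752	0.00805805	0
0.14588198	0.0218551	0.13437	0.00685672	0
0.15	0.0199372	0.133313	0.00649851	0
0.15862685	0.0165782	0.131174	0.00580809	0
0.17248517	0.0125754	0.127939	0.00490874	0
0.1875542	0.0095391	0.124675	0.00414864	0
0.2	0.00771692	0.122157	0.00364636	0
0.20393974	0.00723589	0.12139	0.00350473	0
0.22175678	0.0054888	0.118093	0.00295653	0
0.24113039	0.00416353	0.114792	0.00249409	0
0.26219657	0.00315825	0.111495	0.00210397	0
0.28510318	0.0023957	0.108209	0.00177488	0
0.3	0.00202513	0.106219	0.00160047	0
0.310011	0.00181726	0.104941	0.00149622	0
0.33709488	0.00137848	0.101698	0.00125994	0
0.36654493	0.00104565	0.0984837	0.00106097	0
0.39856785	0.000793179	0.0953042	0.000893427	0
0.4	0.000783848	0.0951689	0.000886875	0
0.43338843	0.000601667	0.0921633	0.00085884	0
0.47125109	0.000456395	0.0890645	0.000830497	0
0.5	0.000375395	0.0869006	0.000811024	0
0.511	0.000349387	0.0861112	0.000774106	0
0.51242159	0.000346199	0.0860107	0.000769516	0
0.55718892	0.00026261	0.0830044	0.000643196	0
0.6	0.000205703	0.0803885	0.00054893	0
0.60586731	0.000199203	0.0800476	0.000544283	0
0.65879846	0.000151106	0.0771421	0.000505875	0
0.71635389	0.000114621	0.0742893	0.000470178	0
0.77893761	8.69462e-05	0.0714904	0.000436999	0
0.8	7.96195e-05	0.0706103	0.00042693	0
0.84698892	6.59531e-05	0.0687465	0.000439878	0
0.92098547	5.00288e-05	0.0660586	0.000459594	0
1	3.81309e-05	0.0634724	0.000479829	0
1.0014467	3.79494e-05	0.0634275	0.000479645	0
1.022	3.54891e-05	0.062798	0.000477067	3.69629e-21
1.0889373	2.87866e-05	0.0608541	0.000469105	1.19716e-07
1.17	2.27146e-05	0.0586948	0.000460253	1.29393e-06
1.1840715	2.18361e-05	0.0583394	0.000458796	1.6992e-06
1.25	1.82614e-05	0.0567442	0.000452248	4.73069e-06
1.287517	1.65638e-05	0.0558842	0.000487523	7.47129e-06
1.33	1.48814e-05	0.0549487	0.000529423	1.16619e-05
1.4	1.25645e-05	0.0534892	0.000603088	2.15571e-05
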