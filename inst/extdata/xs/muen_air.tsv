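# Mass energy-absorption coefficients (cm^2/g) for air, transcribed from Hubbell & Seltzer (1995).
energy_mev	muen_over_rho
0.01	4.742
0.015	1.334
0.02	0.5389
0.03	0.1537
0.04	0.06833
0.05	0.04098
0.06	0.03041
0.08	0.02407
0.1	0.02325
0.15	0.02496
0.2	0.02672
0.3	0.02872
0.4	0.02949
0.5	0.02966
0.6	0.02953
0.8	0.02882
1	0.02789
1.25	0.02666
1.5	0.02547
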