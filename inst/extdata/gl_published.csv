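# Consensus Monte Carlo radial dose function g_L(r) for the new-design
# BEBIG Co-60 HDR source in five phantom media (100 cm diameter x 100 cm
# height cylindrical phantom).
r,water,pmma,polystyrene,rw1,solid_water
0.2,1.014,1.016,1.014,1.014,1.014
0.3,1.010,1.012,1.010,1.010,1.010
0.4,1.008,1.010,1.009,1.008,1.009
0.5,1.007,1.008,1.007,1.007,1.007
0.6,1.003,1.004,1.004,1.004,1.003
0.7,1.002,1.003,1.002,1.002,1.002
0.8,1.001,1.002,1.001,1.001,1.001
0.9,1.001,1.002,1.001,1.001,1.001
1,1.000,1.000,1.000,1.000,1.000
1.2,0.996,0.996,0.996,0.997,0.996
1.4,0.992,0.992,0.992,0.993,0.992
1.5,0.992,0.992,0.992,0.993,0.992
1.8,0.987,0.985,0.986,0.987,0.987
2,0.985,0.983,0.986,0.985,0.985
2.5,0.979,0.976,0.979,0.979,0.979
3,0.972,0.965,0.970,0.972,0.971
3.5,0.960,0.957,0.962,0.961,0.961
4,0.957,0.946,0.957,0.957,0.957
4.5,0.947,0.939,0.948,0.949,0.948
5,0.940,0.932,0.941,0.940,0.940
6,0.926,0.919,0.928,0.926,0.927
7,0.918,0.905,0.920,0.918,0.918
8,0.900,0.880,0.905,0.900,0.901
9,0.882,0.866,0.883,0.883,0.882
10,0.860,0.840,0.871,0.862,0.863
11,0.841,0.818,0.852,0.845,0.844
12,0.820,0.799,0.830,0.822,0.821
13,0.799,0.770,0.809,0.802,0.801
14,0.788,0.749,0.796,0.789,0.786
15,0.759,0.732,0.772,0.763,0.760
18,0.708,0.665,0.716,0.705,0.703
20,0.663,0.625,0.681,0.658,0.657
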