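# wildtrace coefficient table v1
# Mass attenuation coefficients mu/rho [cm^2/g] vs photon energy [keV],
# reference-style grids (log-log interpolation between rows; K-edge
# discontinuities carried as paired rows).
energy_keV,H,C,N,O,S,Al,Cu,water
1.0,7.217,2211,3311,4590,2429,1185,10570,4078
1.5,2.148,700.2,1083,1549,834.2,402.2,4418,1376
1.5596,2.007,634.8,983.9,1412,763.2,362.1,4099,1263
1.55961,2.007,634.8,983.9,1412,763.2,3957,4099,1263
2.0,1.059,302.6,476.9,694.9,384.7,2263,2154,617.3
2.472,0.7588,169.1,268.9,397.3,235.7,1275,1283,349.9
2.47201,0.7588,169.1,268.9,397.3,2070,1275,1283,349.9
3.0,0.5612,90.33,145.6,217.1,1339,788.0,748.8,192.9
4.0,0.4546,37.78,61.66,93.15,633.8,360.5,347.3,82.78
5.0,0.4193,19.12,31.44,47.90,349.3,193.4,189.9,42.58
6.0,0.4042,10.95,18.09,27.70,214.7,115.3,118.0,24.64
8.0,0.3914,4.576,7.562,11.63,98.60,50.33,52.55,10.37
8.9789,0.3880,3.333,5.461,8.389,72.24,36.35,38.29,7.613
8.97891,0.3880,3.333,5.461,8.389,72.24,36.35,278.4,7.613
10.0,0.3854,2.373,3.879,5.952,52.92,26.23,215.9,5.329
15.0,0.3764,0.8071,1.236,1.836,16.91,7.955,74.05,1.673
20.0,0.3695,0.4420,0.6178,0.8651,7.541,3.441,33.79,0.8096
30.0,0.3570,0.2562,0.3066,0.3779,2.468,1.128,10.92,0.3756
40.0,0.3458,0.2076,0.2288,0.2585,1.188,0.5685,4.862,0.2683
50.0,0.3355,0.1871,0.1980,0.2132,0.7166,0.3681,2.613,0.2269
60.0,0.3260,0.1753,0.1817,0.1907,0.5064,0.2778,1.593,0.2059
80.0,0.3091,0.1610,0.1639,0.1678,0.3403,0.2018,0.7630,0.1837
100.0,0.2944,0.1514,0.1529,0.1551,0.2743,0.1704,0.4584,0.1707
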