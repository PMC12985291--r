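# wildtrace coefficient table v1
# Mass energy-absorption coefficients mu_en/rho [cm^2/g] vs photon
# energy [keV] for dry air and liquid water (log-log interpolation).
energy_keV,air,water
1.0,3599,4065
1.5,1188,1372
2.0,526.2,615.2
3.0,161.4,191.7
4.0,76.36,81.91
5.0,39.31,41.88
6.0,22.70,23.97
8.0,9.446,9.915
10.0,4.742,4.944
15.0,1.334,1.374
20.0,0.5389,0.5503
30.0,0.1537,0.1557
40.0,0.06833,0.06947
50.0,0.04098,0.04223
60.0,0.03041,0.03190
80.0,0.02407,0.02597
100.0,0.02325,0.02546
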