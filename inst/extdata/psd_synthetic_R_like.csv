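diameter_um,cum_mass_fraction
0.0650572,0.001
0.0998484,0.005
0.122906,0.01
0.172561,0.0275
0.207859,0.045
0.237738,0.0625
0.264711,0.08
0.289899,0.0975
0.313915,0.115
0.33714,0.1325
0.359831,0.15
0.382176,0.1675
0.404314,0.185
0.426359,0.2025
0.448402,0.22
0.470524,0.2375
0.492794,0.255
0.515275,0.2725
0.538028,0.29
0.561107,0.3075
0.584569,0.325
0.608466,0.3425
0.632855,0.36
0.657791,0.3775
0.683332,0.395
0.709539,0.4125
0.736477,0.43
0.764215,0.4475
0.792826,0.465
0.822392,0.4825
0.853,0.5
0.884747,0.5175
0.917741,0.535
0.9521,0.5525
0.987959,0.57
1.02547,0.5875
1.0648,0.605
1.10614,0.6225
1.14972,0.64
1.19581,0.6575
1.24469,0.675
1.29674,0.6925
1.35236,0.71
1.41208,0.7275
1.4765,0.745
1.54638,0.7625
1.62267,0.78
1.70657,0.7975
1.79961,0.815
1.90386,0.8325
2.02208,0.85
2.15818,0.8675
2.31786,0.885
2.50987,0.9025
2.74869,0.92
3.06055,0.9375
3.50049,0.955
4.21653,0.9725
5.92006,0.99
7.28714,0.995
11.1841,1
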