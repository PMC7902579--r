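energy_MeV,value
0.015,1.47E-15
0.02,1.71E-15
0.03,2.21E-15
0.04,2.40E-15
0.05,2.81E-15
0.06,3.31E-15
0.07,3.79E-15
0.08,4.36E-15
0.1,5.55E-15
0.15,8.68E-15
0.2,1.20E-14
0.3,1.87E-14
0.5,3.21E-14
0.7,4.56E-14
1.0,6.58E-14
1.5,9.80E-14
2.0,1.32E-13
3.0,1.96E-13
6.0,3.19E-12
10.0,4.81E-12
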