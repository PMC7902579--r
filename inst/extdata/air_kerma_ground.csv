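energy_MeV,value
0.015,7.29E-19
0.02,7.42E-18
0.03,2.60E-17
0.04,3.51E-17
0.05,3.94E-17
0.06,4.53E-17
0.07,5.09E-17
0.08,5.78E-17
0.1,7.41E-17
0.15,1.20E-16
0.2,1.68E-16
0.3,2.62E-16
0.4,3.51E-16
0.5,4.39E-16
0.6,5.22E-16
0.8,6.78E-16
1.0,8.26E-16
1.5,1.15E-15
2.0,1.45E-15
3.0,1.98E-15
4.0,2.47E-15
5.0,2.93E-15
6.0,3.37E-15
8.0,4.19E-15
10.0,5.07E-15
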