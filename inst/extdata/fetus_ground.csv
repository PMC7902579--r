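energy_MeV,skin,eyes,lungs,heart,kidneys,liver,stomach,brain,skeleton,total_body
0.015,7.00E-23,0.00E+00,4.37E-24,0.00E+00,7.84E-24,4.48E-24,0.00E+00,2.77E-23,5.12E-23,2.61E-23
0.02,2.98E-20,2.76E-21,1.17E-20,3.89E-21,1.58E-20,1.33E-20,1.61E-21,2.35E-20,3.67E-20,1.79E-20
0.03,1.87E-18,1.04E-18,1.62E-18,1.18E-18,1.72E-18,1.67E-18,8.11E-19,1.73E-18,2.92E-18,1.63E-18
0.04,8.19E-18,5.69E-18,7.98E-18,6.82E-18,8.32E-18,8.22E-18,5.56E-18,7.56E-18,1.31E-17,7.77E-18
0.05,1.58E-17,1.26E-17,1.58E-17,1.50E-17,1.66E-17,1.61E-17,1.24E-17,1.51E-17,2.56E-17,1.56E-17
0.06,2.37E-17,1.96E-17,2.38E-17,2.27E-17,2.47E-17,2.41E-17,2.06E-17,2.31E-17,3.71E-17,2.36E-17
0.07,3.09E-17,2.66E-17,3.10E-17,2.92E-17,3.24E-17,3.17E-17,2.78E-17,3.01E-17,4.69E-17,3.09E-17
0.08,3.79E-17,3.34E-17,3.78E-17,3.62E-17,3.92E-17,3.85E-17,3.22E-17,3.74E-17,5.61E-17,3.79E-17
0.1,5.11E-17,4.63E-17,5.11E-17,4.94E-17,5.33E-17,5.20E-17,4.66E-17,5.01E-17,7.08E-17,5.12E-17
0.15,8.16E-17,7.96E-17,8.22E-17,8.10E-17,8.34E-17,8.33E-17,7.58E-17,8.15E-17,1.03E-16,8.22E-17
0.2,1.12E-16,1.04E-16,1.13E-16,1.08E-16,1.14E-16,1.13E-16,1.09E-16,1.12E-16,1.31E-16,1.12E-16
0.3,1.72E-16,1.62E-16,1.72E-16,1.66E-16,1.73E-16,1.72E-16,1.69E-16,1.70E-16,1.90E-16,1.71E-16
0.4,2.32E-16,2.29E-16,2.33E-16,2.30E-16,2.38E-16,2.32E-16,2.17E-16,2.27E-16,2.44E-16,2.30E-16
0.5,2.92E-16,2.86E-16,2.93E-16,2.84E-16,2.98E-16,2.95E-16,2.80E-16,2.89E-16,3.03E-16,2.91E-16
0.6,3.53E-16,3.30E-16,3.51E-16,3.47E-16,3.59E-16,3.54E-16,3.42E-16,3.45E-16,3.62E-16,3.49E-16
0.7,4.11E-16,3.89E-16,4.08E-16,4.08E-16,4.17E-16,4.14E-16,4.02E-16,4.01E-16,4.17E-16,4.07E-16
0.8,4.70E-16,4.48E-16,4.65E-16,4.69E-16,4.75E-16,4.73E-16,4.62E-16,4.58E-16,4.72E-16,4.64E-16
1.0,5.87E-16,5.74E-16,5.90E-16,5.73E-16,5.85E-16,5.79E-16,5.60E-16,5.78E-16,5.96E-16,5.83E-16
1.1,6.36E-16,6.05E-16,6.29E-16,6.07E-16,6.30E-16,6.31E-16,6.21E-16,6.25E-16,6.35E-16,6.30E-16
1.3,7.53E-16,7.86E-16,7.52E-16,7.60E-16,7.50E-16,7.59E-16,7.04E-16,7.40E-16,7.57E-16,7.48E-16
1.5,8.54E-16,8.23E-16,8.48E-16,8.26E-16,8.55E-16,8.46E-16,8.49E-16,8.40E-16,8.42E-16,8.47E-16
2.0,1.11E-15,1.04E-15,1.09E-15,1.09E-15,1.12E-15,1.13E-15,1.09E-15,1.10E-15,1.09E-15,1.11E-15
3.0,1.60E-15,1.59E-15,1.61E-15,1.60E-15,1.61E-15,1.59E-15,1.51E-15,1.61E-15,1.58E-15,1.60E-15
4.0,2.06E-15,2.04E-15,2.09E-15,2.07E-15,2.10E-15,2.10E-15,2.10E-15,2.05E-15,2.05E-15,2.07E-15
5.0,2.48E-15,2.44E-15,2.50E-15,2.48E-15,2.43E-15,2.48E-15,2.44E-15,2.45E-15,2.44E-15,2.47E-15
6.0,2.90E-15,2.88E-15,2.89E-15,2.82E-15,2.83E-15,2.86E-15,2.96E-15,2.95E-15,2.90E-15,2.90E-15
7.0,3.23E-15,3.33E-15,3.27E-15,3.18E-15,3.21E-15,3.20E-15,3.16E-15,3.29E-15,3.25E-15,3.23E-15
8.0,3.56E-15,3.78E-15,3.64E-15,3.54E-15,3.59E-15,3.54E-15,3.36E-15,3.62E-15,3.60E-15,3.57E-15
10.0,4.34E-15,4.27E-15,4.30E-15,4.17E-15,4.37E-15,4.32E-15,4.40E-15,4.29E-15,4.23E-15,4.32E-15
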