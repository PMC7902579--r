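energy_MeV,skin,eyes,lungs,heart,kidneys,liver,stomach,brain,skeleton,total_body
0.015,8.85E-19,0.00E+00,6.97E-20,0.00E+00,2.63E-19,1.75E-19,0.00E+00,7.66E-21,4.77E-20,3.12E-19
0.02,1.67E-17,1.95E-18,7.59E-18,2.88E-18,1.55E-17,1.16E-17,2.10E-18,1.52E-18,5.36E-18,9.39E-18
0.03,2.09E-16,8.66E-17,1.89E-16,1.53E-16,2.48E-16,2.38E-16,1.11E-16,8.44E-17,2.02E-16,1.74E-16
0.04,5.56E-16,3.22E-16,5.49E-16,4.78E-16,6.62E-16,6.37E-16,4.22E-16,3.26E-16,6.79E-16,5.08E-16
0.05,9.96E-16,6.78E-16,1.01E-15,9.49E-16,1.17E-15,1.12E-15,8.13E-16,7.03E-16,1.33E-15,9.49E-16
0.06,1.48E-15,1.10E-15,1.49E-15,1.43E-15,1.71E-15,1.65E-15,1.30E-15,1.12E-15,2.00E-15,1.43E-15
0.07,1.93E-15,1.52E-15,1.92E-15,1.91E-15,2.11E-15,2.10E-15,1.70E-15,1.51E-15,2.64E-15,1.87E-15
0.08,2.40E-15,1.98E-15,2.44E-15,2.35E-15,2.64E-15,2.62E-15,2.18E-15,1.97E-15,3.25E-15,2.35E-15
0.1,3.30E-15,2.86E-15,3.35E-15,3.24E-15,3.65E-15,3.58E-15,2.93E-15,2.78E-15,4.33E-15,3.25E-15
0.15,5.41E-15,4.75E-15,5.45E-15,5.32E-15,5.74E-15,5.73E-15,5.09E-15,4.70E-15,6.66E-15,5.34E-15
0.2,7.50E-15,6.58E-15,7.47E-15,7.28E-15,7.96E-15,7.83E-15,7.03E-15,6.58E-15,8.75E-15,7.38E-15
0.3,1.17E-14,1.00E-14,1.19E-14,1.17E-14,1.25E-14,1.23E-14,1.17E-14,1.05E-14,1.29E-14,1.16E-14
0.5,2.03E-14,1.87E-14,2.02E-14,1.98E-14,2.13E-14,2.12E-14,2.02E-14,1.84E-14,2.12E-14,2.00E-14
0.7,2.90E-14,2.69E-14,2.97E-14,2.91E-14,3.10E-14,3.06E-14,2.83E-14,2.66E-14,2.95E-14,2.88E-14
1.0,4.36E-14,4.08E-14,4.37E-14,4.36E-14,4.45E-14,4.51E-14,4.56E-14,3.99E-14,4.28E-14,4.29E-14
1.5,6.73E-14,5.91E-14,6.62E-14,6.61E-14,6.97E-14,6.87E-14,6.57E-14,6.15E-14,6.55E-14,6.66E-14
2.0,9.40E-14,8.79E-14,9.59E-14,9.23E-14,9.95E-14,9.81E-14,8.96E-14,8.76E-14,9.08E-14,9.31E-14
3.0,1.47E-13,1.51E-13,1.48E-13,1.56E-13,1.54E-13,1.52E-13,1.44E-13,1.41E-13,1.44E-13,1.46E-13
6.0,3.08E-13,3.06E-13,3.02E-13,3.21E-13,3.16E-13,3.12E-13,2.93E-13,2.99E-13,3.01E-13,3.07E-13
10.0,5.14E-13,4.84E-13,5.18E-13,5.09E-13,5.12E-13,5.23E-13,4.93E-13,5.01E-13,4.98E-13,5.12E-13
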