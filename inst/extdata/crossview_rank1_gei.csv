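gallery,p0,p36,p72,p90,p108,p144,p180,printed_mean
0,98.28,6.10,0.47,0.16,1.10,3.60,31.77,20.21
36,10.49,96.40,19.72,9.23,10.64,28.33,4.85,25.67
72,2.50,15.65,96.09,84.66,49.77,9.70,1.10,37.07
90,1.25,8.14,77.78,97.18,70.42,8.61,1.56,37.85
108,1.72,7.67,50.70,71.83,95.62,15.81,0.78,34.88
144,5.48,26.92,8.45,7.20,18.47,96.40,9.08,24.57
180,34.12,3.29,0.47,0.47,0.47,10.80,98.28,21.13
printed_mean,21.98,23.45,36.24,38.68,35.21,24.75,21.06,28.77
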