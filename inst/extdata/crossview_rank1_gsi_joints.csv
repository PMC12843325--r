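gallery,p0,p36,p72,p90,p108,p144,p180,printed_mean
0,75.26,11.81,8.55,9.43,12.14,9.93,31.77,22.70
36,18.53,72.96,23.44,10.26,16.63,18.33,4.85,23.57
72,10.33,18.65,74.21,54.66,49.77,9.70,5.10,31.77
90,10.89,8.14,57.78,77.20,50.42,8.61,9.16,31.74
108,11.57,12.67,45.70,51.83,74.48,25.81,10.78,33.26
144,9.61,26.92,8.45,7.20,28.47,74.13,13.08,24.01
180,33.26,8.29,6.47,9.47,11.47,18.80,74.96,23.25
printed_mean,24.21,22.78,32.09,30.01,34.74,23.62,21.39,26.98
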