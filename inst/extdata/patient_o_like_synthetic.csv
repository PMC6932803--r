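week,load_cm3,err_cm3
0,50,14.1991540618582
3,61.9066241207229,16.6064448989909
6,58.6825557620904,15.6467427707064
9,0.00273493939087692,0.0539628698519868
12,0.00100818500108584,0.00224775350626141
18,0.0129250670094433,0.0451184434828558
24,0.202795974056721,0.4444290327025
30,1.74856542210218,1.59599683368777
36,7.32040259672328,3.53478940552847
42,12.3669768690395,5.83731251966333
48,19.226319350145,7.49202312793082
54,21.4165895914114,7.9985793409941
60,20.7544044425075,7.80179894414361
66,19.2055526183651,7.38223047089778
72,15.3325918220941,6.95059949621488
78,17.4285670053145,6.57736994783787
84,14.7101730844088,6.28248001701261
90,11.8425401918937,6.06606065633509
96,13.9017275945665,5.91909216956972
102,15.1556751309861,5.82829101712129
108,14.0121610485397,5.77915884013992
114,13.0419732921696,5.75812456357315
120,12.1848600877092,5.75391589573298
126,13.9677494093994,5.7581720842504
132,12.8408180984062,5.76540168246636
138,12.1648925345104,5.7725009143025
144,13.2545714665791,5.77808489026556
150,12.904664423221,5.78183642127833
156,13.2290156017109,5.78398873640059
162,12.5516823897806,5.78497613084348
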