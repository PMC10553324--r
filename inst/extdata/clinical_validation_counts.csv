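acquisition,tn,tp,fn,fp,sens_pub,spec_pub,acc_pub
1,49,29,2,4,0.94,0.92,0.93
2,54,24,3,3,0.89,0.95,0.93
3,32,26,4,4,0.87,0.89,0.88
4,51,19,2,2,0.90,0.96,0.95
5,56,17,7,6,0.71,0.90,0.85
6,50,16,8,8,0.67,0.86,0.80
7,39,11,1,1,0.92,0.98,0.96
8,46,20,6,2,0.77,0.96,0.89
9,48,27,5,2,0.84,0.96,0.91
10,46,16,1,1,0.94,0.98,0.97
11,55,21,7,7,0.75,0.89,0.84
12,48,20,2,2,0.91,0.96,0.94
13,64,22,4,2,0.85,0.97,0.93
14,61,26,3,2,0.90,0.97,0.95
15,55,23,4,2,0.85,0.96,0.93
16,53,33,2,2,0.85,0.96,0.93
17,58,27,4,1,0.87,0.98,0.94
18,59,20,3,4,0.87,0.94,0.92
19,56,19,3,6,0.86,0.90,0.89
20,57,28,3,2,0.90,0.97,0.94
21,48,27,6,5,0.82,0.91,0.87
22,52,25,3,4,0.89,0.93,0.92
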