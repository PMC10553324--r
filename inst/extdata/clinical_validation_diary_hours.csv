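acquisition,diary_off_h,diary_on_h,diary_on_td_h,diary_sleep_h
1,4,11.5,0,5.5
2,2.5,11.5,0,7.5
3,2,13,0,1.5
4,2,8.5,0,8
5,1.5,10,0,10
6,2.5,10.5,0,7.5
7,1.5,4.5,0,7
8,3,9,1,6.5
9,1,15,0,4.5
10,1,7.5,0,6.5
11,3.5,10.5,0.5,8.5
12,2.5,8.5,0,7
13,8,4,1,10
14,3.5,11,0,8.5
15,7.5,6,0,7.5
16,1.5,16,0,5
17,2.5,12,0,9.5
18,4.5,9.5,0,10
19,2.5,11.5,0,10
20,2,14,0,8
21,3.5,13.5,0,7
22,4.5,11,0,8.5
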