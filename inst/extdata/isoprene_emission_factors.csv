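pft,epsilon_ug_m2_h
1,600
2,3000
3,1
4,7000
5,10000
6,7000
7,10000
8,11000
9,2000
10,4000
11,4000
12,1600
13,800
14,200
15,1
16,1
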