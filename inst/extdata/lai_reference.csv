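pft,lai_ref
1,5.0
2,5.0
3,4.0
4,5.5
5,4.5
6,4.0
7,4.5
8,4.0
9,2.0
10,2.0
11,2.0
12,1.5
13,2.0
14,2.0
15,3.0
16,3.0
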