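state_id,mean,ci_low,ci_high
1,0.95,0.94,0.97
2,0.94,0.91,0.97
3,0.89,0.85,0.93
4,0.89,0.89,0.93
5,0.85,0.80,0.91
6,0.89,0.85,0.94
7,0.89,0.85,0.94
8,0.96,0.94,0.98
9,0.85,0.80,0.90
10,0.85,0.81,0.90
11,NA,NA,NA
12,0.96,0.94,0.98
13,0.95,0.93,0.98
14,0.82,0.77,0.87
15,0.88,0.84,0.91
16,0.94,0.91,0.97
17,0.57,0.50,0.64
18,0.42,0.34,0.50
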