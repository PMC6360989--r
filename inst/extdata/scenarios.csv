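"scenario","p1","p2","p3","p4","p5","p6"
1,0.05,0.1,0.2,0.3,0.5,0.7
2,0.09,0.16,0.27,0.38,0.57,0.75
3,0.3,0.4,0.52,0.61,0.76,0.87
4,0,0,0.04,0.09,0.25,0.49
5,0.2,0.9,0.9,0.9,0.9,0.9
6,0.1,0.2,0.9,0.9,0.9,0.9
7,0.3,0.3,0.5,0.5,0.5,0.5
8,0,0,0.03,0.05,0.11,0.33
9,0.12,0.18,0.22,0.25,0.33,0.5
10,0.1,0.1,0.2,0.2,0.4,0.4
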