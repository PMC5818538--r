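case,dsc,sensitivity,specificity
1,0.84,0.92,0.95
2,0.87,0.82,0.99
3,0.87,0.91,0.97
4,0.87,0.90,0.98
5,0.87,0.81,0.99
6,0.89,0.88,0.98
7,0.87,0.84,0.99
8,0.90,0.87,0.99
9,0.92,0.91,0.99
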