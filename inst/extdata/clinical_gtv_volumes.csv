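case,v_manual_cm3,v_auto_cm3
1,196.20,234.63
2,37.59,33.51
3,199.33,216.71
4,131.40,140.70
5,157.12,134.47
6,194.37,189.01
7,119.63,111.62
8,155.97,145.91
9,145.98,143.55
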