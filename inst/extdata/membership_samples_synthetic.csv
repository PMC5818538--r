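modality,mean,sd,source
ADC,1.189,0.295,synthetic-clinical-1
ADC,1.804,0.233,synthetic-clinical-2
ADC,2.018,0.088,synthetic-clinical-3
ADC,1.934,0.363,synthetic-clinical-4
ADC,1.431,0.096,synthetic-clinical-5
ADC,1.817,0.344,synthetic-clinical-6
ADC,1.064,0.274,synthetic-clinical-7
ADC,1.581,0.306,synthetic-clinical-8
ADC,1.255,0.102,synthetic-clinical-9
ADC,1.346,0.086,synthetic-clinical-10
ADC,2.034,0.117,synthetic-clinical-11
ADC,1.055,0.151,synthetic-clinical-12
ADC,1.77,0.175,synthetic-clinical-13
ADC,1.972,0.187,synthetic-clinical-14
ADC,1.834,0.312,synthetic-clinical-15
ADC,1.713,0.126,synthetic-clinical-16
ADC,1.996,0.37,synthetic-literature-1
ADC,1.999,0.166,synthetic-literature-2
ADC,1.133,0.357,synthetic-literature-3
ADC,2.092,0.282,synthetic-literature-4
ADC,1.113,0.31,synthetic-literature-5
ADC,1.809,0.197,synthetic-literature-6
ADC,1.638,0.169,synthetic-literature-7
ADC,1.626,0.148,synthetic-literature-8
ADC,1.265,0.216,synthetic-literature-9
ADC,1.307,0.399,synthetic-literature-10
ADC,1.217,0.232,synthetic-literature-11
ADC,1.216,0.184,synthetic-literature-12
ADC,1.371,0.335,synthetic-literature-13
ADC,1.796,0.263,synthetic-literature-14
ADC,1.181,0.113,synthetic-literature-15
ADC,1.667,0.164,synthetic-literature-16
FA,0.156,0.059,synthetic-clinical-1
FA,0.1,0.04,synthetic-clinical-2
FA,0.28,0.068,synthetic-clinical-3
FA,0.09,0.066,synthetic-clinical-4
FA,0.242,0.048,synthetic-clinical-5
FA,0.218,0.022,synthetic-clinical-6
FA,0.086,0.031,synthetic-clinical-7
FA,0.084,0.03,synthetic-clinical-8
FA,0.123,0.056,synthetic-clinical-9
FA,0.255,0.052,synthetic-clinical-10
FA,0.137,0.079,synthetic-clinical-11
FA,0.133,0.032,synthetic-clinical-12
FA,0.192,0.058,synthetic-clinical-13
FA,0.282,0.048,synthetic-clinical-14
FA,0.273,0.029,synthetic-clinical-15
FA,0.228,0.039,synthetic-clinical-16
FA,0.277,0.033,synthetic-literature-1
FA,0.247,0.075,synthetic-literature-2
FA,0.266,0.072,synthetic-literature-3
FA,0.173,0.071,synthetic-literature-4
FA,0.298,0.046,synthetic-literature-5
CBV_RATIO,5.388,0.547,synthetic-clinical-1
CBV_RATIO,1.116,0.596,synthetic-clinical-2
CBV_RATIO,3.113,1.094,synthetic-clinical-3
CBV_RATIO,3.711,0.39,synthetic-clinical-4
CBV_RATIO,1.958,0.907,synthetic-clinical-5
CBV_RATIO,1.101,0.653,synthetic-clinical-6
CBV_RATIO,4.705,0.926,synthetic-clinical-7
CBV_RATIO,4.358,0.773,synthetic-clinical-8
CBV_RATIO,3.285,0.945,synthetic-clinical-9
CBV_RATIO,3.58,0.636,synthetic-clinical-10
CBV_RATIO,1.945,0.943,synthetic-clinical-11
CBV_RATIO,3.056,0.941,synthetic-clinical-12
CBV_RATIO,3.62,1.018,synthetic-literature-1
CBV_RATIO,2.163,0.66,synthetic-literature-2
CBV_RATIO,2.876,0.319,synthetic-literature-3
CBV_RATIO,3.494,1.167,synthetic-literature-4
CBV_RATIO,1.196,1.193,synthetic-literature-5
CBV_RATIO,2.436,0.654,synthetic-literature-6
CBV_RATIO,4.415,0.621,synthetic-literature-7
CBV_RATIO,2.337,1.187,synthetic-literature-8
CBV_RATIO,2.48,0.988,synthetic-literature-9
CBV_RATIO,1.536,0.788,synthetic-literature-10
CBV_RATIO,1.525,0.436,synthetic-literature-11
CBV_RATIO,4.007,0.782,synthetic-literature-12
CBV_RATIO,1.654,0.442,synthetic-literature-13
CBV_RATIO,3.548,0.473,synthetic-literature-14
CBV_RATIO,4.029,0.84,synthetic-literature-15
CBV_RATIO,5.426,1.149,synthetic-literature-16
CBV_RATIO,4.854,0.409,synthetic-literature-17
CBV_RATIO,1.668,0.318,synthetic-literature-18
CBV_RATIO,2.028,1.018,synthetic-literature-19
CBV_RATIO,4.216,0.399,synthetic-literature-20
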