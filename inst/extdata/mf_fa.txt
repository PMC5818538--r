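# Tumour membership model: FA (dimensionless), scaled sigmoid difference
modality: FA
form: sigmoid_diff
coefficients: 1.1 60 0.06 15.76 0.27
domain: 0 1
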