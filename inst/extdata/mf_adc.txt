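# Tumour membership model: ADC (units 1e-3 mm^2/s), sum of two Gaussians
modality: ADC
form: gaussian2
coefficients: 0.5 1.5 0.33 0.5 1.57 0.66
domain: 0 4
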