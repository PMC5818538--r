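# Tumour membership model: rCBV ratio vs contralateral WM, sum of two Gaussians
modality: CBV_RATIO
form: gaussian2
coefficients: 0.65 1.1 0.8 0.5 2.68 2.37
domain: 0 20
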