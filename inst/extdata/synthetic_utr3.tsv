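id	utr3_start
synthetic_lbp_like	240
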