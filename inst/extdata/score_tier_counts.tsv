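tier	responders	total
low	1	42
intermediate	11	78
high	36	78
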