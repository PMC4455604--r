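code	x	y
A	155.5	361
B	544.5	361
AB	350	350
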