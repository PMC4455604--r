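label	x	y
A	350	67
B	83.264	528.999
C	616.736	528.999
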