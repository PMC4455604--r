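label	x	y
A	14	267.99
B	362.604	14
C	686	258.765
D	572.715	671.582
E	133.574	676.377
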