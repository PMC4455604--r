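label	x	y
A	14	301.738
B	107.982	176.672
C	587.817	176.671
D	683.765	301.737
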