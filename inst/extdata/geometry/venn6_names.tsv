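label	x	y
A	18.929	684.193
B	684.199	18.937
C	468.732	468.855
D	522.473	506.656
E	514.709	514.802
F	514.709	514.802
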