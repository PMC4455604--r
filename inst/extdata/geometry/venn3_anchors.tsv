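code	x	y
A	349	171.5
B	172.5	475
C	527.5	475
AB	229.5	305.25
AC	470.5	305.25
BC	350	514.25
ABC	350	375
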