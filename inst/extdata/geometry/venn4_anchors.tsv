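code	x	y
A	113.75	435.75
B	253.5	194.75
C	442.5	194.75
D	586	430.25
AB	157.5	277.5
AC	208.5	498
AD	348	583
BC	348	239.5
BD	487.5	498
CD	538.25	277.5
ABC	250.25	333.25
ABD	439.5	527.25
ACD	256.25	527.25
BCD	432.75	316.5
ABCD	348	443.75
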