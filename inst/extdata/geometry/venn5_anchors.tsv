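code	x	y
A	68.25	277
B	371	72.5
C	639	286.5
D	519.5	623.75
E	164.25	606
AB	188.5	210.25
AC	119.5	369.5
AD	541.5	512.75
AE	151.25	485.25
BC	460.75	167.75
BD	287	149.5
BE	277.5	592.75
CD	582.25	401.25
CE	544.75	242.5
DE	388	603.75
ABC	174.75	322.75
ABD	219.75	195.25
ABE	252.5	530.75
ACD	567.25	440
ACE	140.75	442.75
ADE	468.5	519.25
BCD	343	189
BCE	487.75	195.25
BDE	352	596.25
CDE	528.25	307
ABCD	235.25	242.25
ABCE	195.25	451
ABDE	371.75	549.75
ACDE	527.75	403.25
BCDE	443	221.5
ABCDE	354	374
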