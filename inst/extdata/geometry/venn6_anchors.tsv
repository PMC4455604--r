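code	x	y
A	128.25	571.5
B	571.5	128.25
C	366.75	485.25
D	506.75	467.25
E	449.75	518
F	411.75	537
AB	128.25	128.25
AC	214.75	366.75
AD	232.75	506.75
AE	182	449.75
AF	163	411.75
BC	485.25	333.25
BD	467.25	193.25
BE	518	250.25
BF	537	288.25
CD	457.75	433.75
CE	416.5	467
CF	392.75	479.5
DE	534.5	397.25
DF	528.25	439.75
EF	478.5	499
ABC	333.25	214.75
ABD	193.25	232.75
ABE	250.25	182
ABF	288.25	163
ACD	266.25	457.75
ACE	233	416.5
ACF	220.5	392.75
ADE	302.75	534.5
ADF	260.25	528.25
AEF	201	478.5
BCD	433.75	242.25
BCE	467	283.5
BCF	479.5	307.25
BDE	397.25	165.5
BDF	439.75	171.75
BEF	499	221.5
CDE	478.5	385.5
CDF	472.25	411.5
CEF	439.25	453.5
DEF	549.25	365
ABCD	242.25	266.25
ABCE	283.5	233
ABCF	307.25	220.5
ABDE	165.5	302.75
ABDF	171.75	260.25
ABEF	221.5	201
ACDE	314.5	478.5
ACDF	288.5	472.25
ACEF	246.5	439.25
ADEF	335	549.25
BCDE	385.5	221.5
BCDF	411.5	227.75
BCEF	453.5	260.75
BDEF	365	150.75
CDEF	389.25	389.25
ABCDE	221.5	314.5
ABCDF	227.75	288.5
ABCEF	260.75	246.5
ABDEF	150.75	335
ACDEF	310.5	389.25
BCDEF	389.25	310.5
ABCDEF	310.75	310.5
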