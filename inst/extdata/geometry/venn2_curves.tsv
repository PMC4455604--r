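label	vertex	x	y
A	1	450	350
A	2	449.582	362.754
A	3	448.332	375.453
A	4	446.253	388.043
A	5	443.356	400.47
A	6	439.651	412.681
A	7	435.157	424.623
A	8	429.89	436.246
A	9	423.875	447.5
A	10	417.137	458.336
A	11	409.704	468.708
A	12	401.609	478.572
A	13	392.886	487.886
A	14	383.572	496.609
A	15	373.708	504.704
A	16	363.336	512.137
A	17	352.5	518.875
A	18	341.246	524.89
A	19	329.623	530.157
A	20	317.681	534.651
A	21	305.47	538.356
A	22	293.043	541.253
A	23	280.453	543.332
A	24	267.754	544.582
A	25	255	545
A	26	242.246	544.582
A	27	229.547	543.332
A	28	216.957	541.253
A	29	204.53	538.356
A	30	192.319	534.651
A	31	180.377	530.157
A	32	168.754	524.89
A	33	157.5	518.875
A	34	146.664	512.137
A	35	136.292	504.704
A	36	126.428	496.609
A	37	117.114	487.886
A	38	108.391	478.572
A	39	100.296	468.708
A	40	92.863	458.336
A	41	86.125	447.5
A	42	80.11	436.246
A	43	74.843	424.623
A	44	70.349	412.681
A	45	66.644	400.47
A	46	63.747	388.043
A	47	61.668	375.453
A	48	60.418	362.754
A	49	60	350
A	50	60.418	337.246
A	51	61.668	324.547
A	52	63.747	311.957
A	53	66.644	299.53
A	54	70.349	287.319
A	55	74.843	275.377
A	56	80.11	263.754
A	57	86.125	252.5
A	58	92.863	241.664
A	59	100.296	231.292
A	60	108.391	221.428
A	61	117.114	212.114
A	62	126.428	203.391
A	63	136.292	195.296
A	64	146.664	187.863
A	65	157.5	181.125
A	66	168.754	175.11
A	67	180.377	169.843
A	68	192.319	165.349
A	69	204.53	161.644
A	70	216.957	158.747
A	71	229.547	156.668
A	72	242.246	155.418
A	73	255	155
A	74	267.754	155.418
A	75	280.453	156.668
A	76	293.043	158.747
A	77	305.47	161.644
A	78	317.681	165.349
A	79	329.623	169.843
A	80	341.246	175.11
A	81	352.5	181.125
A	82	363.336	187.863
A	83	373.708	195.296
A	84	383.572	203.391
A	85	392.886	212.114
A	86	401.609	221.428
A	87	409.704	231.292
A	88	417.137	241.664
A	89	423.875	252.5
A	90	429.89	263.754
A	91	435.157	275.377
A	92	439.651	287.319
A	93	443.356	299.53
A	94	446.253	311.957
A	95	448.332	324.547
A	96	449.582	337.246
B	1	640	350
B	2	639.582	362.754
B	3	638.332	375.453
B	4	636.253	388.043
B	5	633.356	400.47
B	6	629.651	412.681
B	7	625.157	424.623
B	8	619.89	436.246
B	9	613.875	447.5
B	10	607.137	458.336
B	11	599.704	468.708
B	12	591.609	478.572
B	13	582.886	487.886
B	14	573.572	496.609
B	15	563.708	504.704
B	16	553.336	512.137
B	17	542.5	518.875
B	18	531.246	524.89
B	19	519.623	530.157
B	20	507.681	534.651
B	21	495.47	538.356
B	22	483.043	541.253
B	23	470.453	543.332
B	24	457.754	544.582
B	25	445	545
B	26	432.246	544.582
B	27	419.547	543.332
B	28	406.957	541.253
B	29	394.53	538.356
B	30	382.319	534.651
B	31	370.377	530.157
B	32	358.754	524.89
B	33	347.5	518.875
B	34	336.664	512.137
B	35	326.292	504.704
B	36	316.428	496.609
B	37	307.114	487.886
B	38	298.391	478.572
B	39	290.296	468.708
B	40	282.863	458.336
B	41	276.125	447.5
B	42	270.11	436.246
B	43	264.843	424.623
B	44	260.349	412.681
B	45	256.644	400.47
B	46	253.747	388.043
B	47	251.668	375.453
B	48	250.418	362.754
B	49	250	350
B	50	250.418	337.246
B	51	251.668	324.547
B	52	253.747	311.957
B	53	256.644	299.53
B	54	260.349	287.319
B	55	264.843	275.377
B	56	270.11	263.754
B	57	276.125	252.5
B	58	282.863	241.664
B	59	290.296	231.292
B	60	298.391	221.428
B	61	307.114	212.114
B	62	316.428	203.391
B	63	326.292	195.296
B	64	336.664	187.863
B	65	347.5	181.125
B	66	358.754	175.11
B	67	370.377	169.843
B	68	382.319	165.349
B	69	394.53	161.644
B	70	406.957	158.747
B	71	419.547	156.668
B	72	432.246	155.418
B	73	445	155
B	74	457.754	155.418
B	75	470.453	156.668
B	76	483.043	158.747
B	77	495.47	161.644
B	78	507.681	165.349
B	79	519.623	169.843
B	80	531.246	175.11
B	81	542.5	181.125
B	82	553.336	187.863
B	83	563.708	195.296
B	84	573.572	203.391
B	85	582.886	212.114
B	86	591.609	221.428
B	87	599.704	231.292
B	88	607.137	241.664
B	89	613.875	252.5
B	90	619.89	263.754
B	91	625.157	275.377
B	92	629.651	287.319
B	93	633.356	299.53
B	94	636.253	311.957
B	95	638.332	324.547
B	96	639.582	337.246
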