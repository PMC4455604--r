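label	vertex	x	y
A	1	51.957	258.018
A	2	58.991	250.473
A	3	66.823	243.655
A	4	75.417	237.592
A	5	84.737	232.31
A	6	94.744	227.832
A	7	105.394	224.176
A	8	116.642	221.359
A	9	128.439	219.393
A	10	140.736	218.286
A	11	153.479	218.042
A	12	166.614	218.664
A	13	180.085	220.147
A	14	193.833	222.487
A	15	207.801	225.672
A	16	221.928	229.689
A	17	236.154	234.521
A	18	250.418	240.147
A	19	264.658	246.544
A	20	278.815	253.683
A	21	292.826	261.535
A	22	306.633	270.065
A	23	320.176	279.237
A	24	333.397	289.012
A	25	346.239	299.348
A	26	358.648	310.2
A	27	370.57	321.523
A	28	381.955	333.268
A	29	392.753	345.383
A	30	402.918	357.819
A	31	412.407	370.52
A	32	421.179	383.434
A	33	429.197	396.504
A	34	436.426	409.674
A	35	442.836	422.889
A	36	448.398	436.091
A	37	453.089	449.225
A	38	456.889	462.233
A	39	459.782	475.061
A	40	461.755	487.653
A	41	462.8	499.955
A	42	462.912	511.915
A	43	462.091	523.481
A	44	460.341	534.604
A	45	457.668	545.236
A	46	454.085	555.332
A	47	449.606	564.848
A	48	444.251	573.745
A	49	438.043	581.982
A	50	431.009	589.527
A	51	423.177	596.345
A	52	414.583	602.408
A	53	405.263	607.69
A	54	395.256	612.168
A	55	384.606	615.824
A	56	373.358	618.641
A	57	361.561	620.607
A	58	349.264	621.714
A	59	336.521	621.958
A	60	323.386	621.336
A	61	309.915	619.853
A	62	296.167	617.513
A	63	282.199	614.328
A	64	268.072	610.311
A	65	253.846	605.479
A	66	239.582	599.853
A	67	225.342	593.456
A	68	211.185	586.317
A	69	197.174	578.465
A	70	183.367	569.935
A	71	169.824	560.763
A	72	156.603	550.988
A	73	143.761	540.652
A	74	131.352	529.8
A	75	119.43	518.477
A	76	108.045	506.732
A	77	97.247	494.617
A	78	87.082	482.181
A	79	77.593	469.48
A	80	68.821	456.566
A	81	60.803	443.496
A	82	53.574	430.326
A	83	47.164	417.111
A	84	41.602	403.909
A	85	36.911	390.775
A	86	33.111	377.767
A	87	30.218	364.939
A	88	28.245	352.347
A	89	27.2	340.045
A	90	27.088	328.085
A	91	27.909	316.519
A	92	29.659	305.396
A	93	32.332	294.764
A	94	35.915	284.668
A	95	40.394	275.152
A	96	45.749	266.255
B	1	121.957	188.018
B	2	128.991	180.473
B	3	136.823	173.655
B	4	145.417	167.592
B	5	154.737	162.31
B	6	164.744	157.832
B	7	175.394	154.176
B	8	186.642	151.359
B	9	198.439	149.393
B	10	210.736	148.286
B	11	223.479	148.042
B	12	236.614	148.664
B	13	250.085	150.147
B	14	263.833	152.487
B	15	277.801	155.672
B	16	291.928	159.689
B	17	306.154	164.521
B	18	320.418	170.147
B	19	334.658	176.544
B	20	348.815	183.683
B	21	362.826	191.535
B	22	376.633	200.065
B	23	390.176	209.237
B	24	403.397	219.012
B	25	416.239	229.348
B	26	428.648	240.2
B	27	440.57	251.523
B	28	451.955	263.268
B	29	462.753	275.383
B	30	472.918	287.819
B	31	482.407	300.52
B	32	491.179	313.434
B	33	499.197	326.504
B	34	506.426	339.674
B	35	512.836	352.889
B	36	518.398	366.091
B	37	523.089	379.225
B	38	526.889	392.233
B	39	529.782	405.061
B	40	531.755	417.653
B	41	532.8	429.955
B	42	532.912	441.915
B	43	532.091	453.481
B	44	530.341	464.604
B	45	527.668	475.236
B	46	524.085	485.332
B	47	519.606	494.848
B	48	514.251	503.745
B	49	508.043	511.982
B	50	501.009	519.527
B	51	493.177	526.345
B	52	484.583	532.408
B	53	475.263	537.69
B	54	465.256	542.168
B	55	454.606	545.824
B	56	443.358	548.641
B	57	431.561	550.607
B	58	419.264	551.714
B	59	406.521	551.958
B	60	393.386	551.336
B	61	379.915	549.853
B	62	366.167	547.513
B	63	352.199	544.328
B	64	338.072	540.311
B	65	323.846	535.479
B	66	309.582	529.853
B	67	295.342	523.456
B	68	281.185	516.317
B	69	267.174	508.465
B	70	253.367	499.935
B	71	239.824	490.763
B	72	226.603	480.988
B	73	213.761	470.652
B	74	201.352	459.8
B	75	189.43	448.477
B	76	178.045	436.732
B	77	167.247	424.617
B	78	157.082	412.181
B	79	147.593	399.48
B	80	138.821	386.566
B	81	130.803	373.496
B	82	123.574	360.326
B	83	117.164	347.111
B	84	111.602	333.909
B	85	106.911	320.775
B	86	103.111	307.767
B	87	100.218	294.939
B	88	98.245	282.347
B	89	97.2	270.045
B	90	97.088	258.085
B	91	97.909	246.519
B	92	99.659	235.396
B	93	102.332	224.764
B	94	105.915	214.668
B	95	110.394	205.152
B	96	115.749	196.255
C	1	573.843	188.018
C	2	580.051	196.255
C	3	585.406	205.152
C	4	589.885	214.668
C	5	593.468	224.764
C	6	596.141	235.396
C	7	597.891	246.519
C	8	598.712	258.085
C	9	598.6	270.045
C	10	597.555	282.347
C	11	595.582	294.939
C	12	592.689	307.767
C	13	588.889	320.775
C	14	584.198	333.909
C	15	578.636	347.111
C	16	572.226	360.326
C	17	564.997	373.496
C	18	556.979	386.566
C	19	548.207	399.48
C	20	538.718	412.181
C	21	528.553	424.617
C	22	517.755	436.732
C	23	506.37	448.477
C	24	494.448	459.8
C	25	482.039	470.652
C	26	469.197	480.988
C	27	455.976	490.763
C	28	442.433	499.935
C	29	428.626	508.465
C	30	414.615	516.317
C	31	400.458	523.456
C	32	386.218	529.853
C	33	371.954	535.479
C	34	357.728	540.311
C	35	343.601	544.328
C	36	329.633	547.513
C	37	315.885	549.853
C	38	302.414	551.336
C	39	289.279	551.958
C	40	276.536	551.714
C	41	264.239	550.607
C	42	252.442	548.641
C	43	241.194	545.824
C	44	230.544	542.168
C	45	220.537	537.69
C	46	211.217	532.408
C	47	202.623	526.345
C	48	194.791	519.527
C	49	187.757	511.982
C	50	181.549	503.745
C	51	176.194	494.848
C	52	171.715	485.332
C	53	168.132	475.236
C	54	165.459	464.604
C	55	163.709	453.481
C	56	162.888	441.915
C	57	163	429.955
C	58	164.045	417.653
C	59	166.018	405.061
C	60	168.911	392.233
C	61	172.711	379.225
C	62	177.402	366.091
C	63	182.964	352.889
C	64	189.374	339.674
C	65	196.603	326.504
C	66	204.621	313.434
C	67	213.393	300.52
C	68	222.882	287.819
C	69	233.047	275.383
C	70	243.845	263.268
C	71	255.23	251.523
C	72	267.152	240.2
C	73	279.561	229.348
C	74	292.403	219.012
C	75	305.624	209.237
C	76	319.167	200.065
C	77	332.974	191.535
C	78	346.985	183.683
C	79	361.142	176.544
C	80	375.382	170.147
C	81	389.646	164.521
C	82	403.872	159.689
C	83	417.999	155.672
C	84	431.967	152.487
C	85	445.715	150.147
C	86	459.186	148.664
C	87	472.321	148.042
C	88	485.064	148.286
C	89	497.361	149.393
C	90	509.158	151.359
C	91	520.406	154.176
C	92	531.056	157.832
C	93	541.063	162.31
C	94	550.383	167.592
C	95	558.977	173.655
C	96	566.809	180.473
D	1	643.843	258.018
D	2	650.051	266.255
D	3	655.406	275.152
D	4	659.885	284.668
D	5	663.468	294.764
D	6	666.141	305.396
D	7	667.891	316.519
D	8	668.712	328.085
D	9	668.6	340.045
D	10	667.555	352.347
D	11	665.582	364.939
D	12	662.689	377.767
D	13	658.889	390.775
D	14	654.198	403.909
D	15	648.636	417.111
D	16	642.226	430.326
D	17	634.997	443.496
D	18	626.979	456.566
D	19	618.207	469.48
D	20	608.718	482.181
D	21	598.553	494.617
D	22	587.755	506.732
D	23	576.37	518.477
D	24	564.448	529.8
D	25	552.039	540.652
D	26	539.197	550.988
D	27	525.976	560.763
D	28	512.433	569.935
D	29	498.626	578.465
D	30	484.615	586.317
D	31	470.458	593.456
D	32	456.218	599.853
D	33	441.954	605.479
D	34	427.728	610.311
D	35	413.601	614.328
D	36	399.633	617.513
D	37	385.885	619.853
D	38	372.414	621.336
D	39	359.279	621.958
D	40	346.536	621.714
D	41	334.239	620.607
D	42	322.442	618.641
D	43	311.194	615.824
D	44	300.544	612.168
D	45	290.537	607.69
D	46	281.217	602.408
D	47	272.623	596.345
D	48	264.791	589.527
D	49	257.757	581.982
D	50	251.549	573.745
D	51	246.194	564.848
D	52	241.715	555.332
D	53	238.132	545.236
D	54	235.459	534.604
D	55	233.709	523.481
D	56	232.888	511.915
D	57	233	499.955
D	58	234.045	487.653
D	59	236.018	475.061
D	60	238.911	462.233
D	61	242.711	449.225
D	62	247.402	436.091
D	63	252.964	422.889
D	64	259.374	409.674
D	65	266.603	396.504
D	66	274.621	383.434
D	67	283.393	370.52
D	68	292.882	357.819
D	69	303.047	345.383
D	70	313.845	333.268
D	71	325.23	321.523
D	72	337.152	310.2
D	73	349.561	299.348
D	74	362.403	289.012
D	75	375.624	279.237
D	76	389.167	270.065
D	77	402.974	261.535
D	78	416.985	253.683
D	79	431.142	246.544
D	80	445.382	240.147
D	81	459.646	234.521
D	82	473.872	229.689
D	83	487.999	225.672
D	84	501.967	222.487
D	85	515.715	220.147
D	86	529.186	218.664
D	87	542.321	218.042
D	88	555.064	218.286
D	89	567.361	219.393
D	90	579.158	221.359
D	91	590.406	224.176
D	92	601.056	227.832
D	93	611.063	232.31
D	94	620.383	237.592
D	95	628.977	243.655
D	96	636.809	250.473
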