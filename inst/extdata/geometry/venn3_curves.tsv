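label	vertex	x	y
A	1	535	270
A	2	534.604	282.1
A	3	533.417	294.147
A	4	531.445	306.092
A	5	528.696	317.882
A	6	525.182	329.466
A	7	520.918	340.796
A	8	515.921	351.823
A	9	510.215	362.5
A	10	503.822	372.78
A	11	496.77	382.621
A	12	489.09	391.979
A	13	480.815	400.815
A	14	471.979	409.09
A	15	462.621	416.77
A	16	452.78	423.822
A	17	442.5	430.215
A	18	431.823	435.921
A	19	420.796	440.918
A	20	409.466	445.182
A	21	397.882	448.696
A	22	386.092	451.445
A	23	374.147	453.417
A	24	362.1	454.604
A	25	350	455
A	26	337.9	454.604
A	27	325.853	453.417
A	28	313.908	451.445
A	29	302.118	448.696
A	30	290.534	445.182
A	31	279.204	440.918
A	32	268.177	435.921
A	33	257.5	430.215
A	34	247.22	423.822
A	35	237.379	416.77
A	36	228.021	409.09
A	37	219.185	400.815
A	38	210.91	391.979
A	39	203.23	382.621
A	40	196.178	372.78
A	41	189.785	362.5
A	42	184.079	351.823
A	43	179.082	340.796
A	44	174.818	329.466
A	45	171.304	317.882
A	46	168.555	306.092
A	47	166.583	294.147
A	48	165.396	282.1
A	49	165	270
A	50	165.396	257.9
A	51	166.583	245.853
A	52	168.555	233.908
A	53	171.304	222.118
A	54	174.818	210.534
A	55	179.082	199.204
A	56	184.079	188.177
A	57	189.785	177.5
A	58	196.178	167.22
A	59	203.23	157.379
A	60	210.91	148.021
A	61	219.185	139.185
A	62	228.021	130.91
A	63	237.379	123.23
A	64	247.22	116.178
A	65	257.5	109.785
A	66	268.177	104.079
A	67	279.204	99.082
A	68	290.534	94.818
A	69	302.118	91.304
A	70	313.908	88.555
A	71	325.853	86.583
A	72	337.9	85.396
A	73	350	85
A	74	362.1	85.396
A	75	374.147	86.583
A	76	386.092	88.555
A	77	397.882	91.304
A	78	409.466	94.818
A	79	420.796	99.082
A	80	431.823	104.079
A	81	442.5	109.785
A	82	452.78	116.178
A	83	462.621	123.23
A	84	471.979	130.91
A	85	480.815	139.185
A	86	489.09	148.021
A	87	496.77	157.379
A	88	503.822	167.22
A	89	510.215	177.5
A	90	515.921	188.177
A	91	520.918	199.204
A	92	525.182	210.534
A	93	528.696	222.118
A	94	531.445	233.908
A	95	533.417	245.853
A	96	534.604	257.9
B	1	444.067	427.5
B	2	443.671	439.6
B	3	442.485	451.647
B	4	440.513	463.592
B	5	437.764	475.382
B	6	434.249	486.966
B	7	429.985	498.296
B	8	424.989	509.323
B	9	419.282	520
B	10	412.889	530.28
B	11	405.838	540.121
B	12	398.158	549.479
B	13	389.882	558.315
B	14	381.046	566.59
B	15	371.688	574.27
B	16	361.848	581.322
B	17	351.567	587.715
B	18	340.891	593.421
B	19	329.864	598.418
B	20	318.534	602.682
B	21	306.949	606.196
B	22	295.159	608.945
B	23	283.215	610.917
B	24	271.167	612.104
B	25	259.067	612.5
B	26	246.968	612.104
B	27	234.92	610.917
B	28	222.976	608.945
B	29	211.186	606.196
B	30	199.601	602.682
B	31	188.271	598.418
B	32	177.244	593.421
B	33	166.567	587.715
B	34	156.287	581.322
B	35	146.446	574.27
B	36	137.088	566.59
B	37	128.253	558.315
B	38	119.977	549.479
B	39	112.297	540.121
B	40	105.245	530.28
B	41	98.853	520
B	42	93.146	509.323
B	43	88.15	498.296
B	44	83.885	486.966
B	45	80.371	475.382
B	46	77.622	463.592
B	47	75.65	451.647
B	48	74.463	439.6
B	49	74.067	427.5
B	50	74.463	415.4
B	51	75.65	403.353
B	52	77.622	391.408
B	53	80.371	379.618
B	54	83.885	368.034
B	55	88.15	356.704
B	56	93.146	345.677
B	57	98.853	335
B	58	105.245	324.72
B	59	112.297	314.879
B	60	119.977	305.521
B	61	128.253	296.685
B	62	137.088	288.41
B	63	146.446	280.73
B	64	156.287	273.678
B	65	166.567	267.285
B	66	177.244	261.579
B	67	188.271	256.582
B	68	199.601	252.318
B	69	211.186	248.804
B	70	222.976	246.055
B	71	234.92	244.083
B	72	246.968	242.896
B	73	259.067	242.5
B	74	271.167	242.896
B	75	283.215	244.083
B	76	295.159	246.055
B	77	306.949	248.804
B	78	318.534	252.318
B	79	329.864	256.582
B	80	340.891	261.579
B	81	351.567	267.285
B	82	361.848	273.678
B	83	371.688	280.73
B	84	381.046	288.41
B	85	389.882	296.685
B	86	398.158	305.521
B	87	405.838	314.879
B	88	412.889	324.72
B	89	419.282	335
B	90	424.989	345.677
B	91	429.985	356.704
B	92	434.249	368.034
B	93	437.764	379.618
B	94	440.513	391.408
B	95	442.485	403.353
B	96	443.671	415.4
C	1	625.933	427.5
C	2	625.537	439.6
C	3	624.35	451.647
C	4	622.378	463.592
C	5	619.629	475.382
C	6	616.115	486.966
C	7	611.85	498.296
C	8	606.854	509.323
C	9	601.147	520
C	10	594.755	530.28
C	11	587.703	540.121
C	12	580.023	549.479
C	13	571.747	558.315
C	14	562.912	566.59
C	15	553.554	574.27
C	16	543.713	581.322
C	17	533.433	587.715
C	18	522.756	593.421
C	19	511.729	598.418
C	20	500.399	602.682
C	21	488.814	606.196
C	22	477.024	608.945
C	23	465.08	610.917
C	24	453.032	612.104
C	25	440.933	612.5
C	26	428.833	612.104
C	27	416.785	610.917
C	28	404.841	608.945
C	29	393.051	606.196
C	30	381.466	602.682
C	31	370.136	598.418
C	32	359.109	593.421
C	33	348.433	587.715
C	34	338.152	581.322
C	35	328.312	574.27
C	36	318.954	566.59
C	37	310.118	558.315
C	38	301.842	549.479
C	39	294.162	540.121
C	40	287.111	530.28
C	41	280.718	520
C	42	275.011	509.323
C	43	270.015	498.296
C	44	265.751	486.966
C	45	262.236	475.382
C	46	259.487	463.592
C	47	257.515	451.647
C	48	256.329	439.6
C	49	255.933	427.5
C	50	256.329	415.4
C	51	257.515	403.353
C	52	259.487	391.408
C	53	262.236	379.618
C	54	265.751	368.034
C	55	270.015	356.704
C	56	275.011	345.677
C	57	280.718	335
C	58	287.111	324.72
C	59	294.162	314.879
C	60	301.842	305.521
C	61	310.118	296.685
C	62	318.954	288.41
C	63	328.312	280.73
C	64	338.152	273.678
C	65	348.433	267.285
C	66	359.109	261.579
C	67	370.136	256.582
C	68	381.466	252.318
C	69	393.051	248.804
C	70	404.841	246.055
C	71	416.785	244.083
C	72	428.833	242.896
C	73	440.933	242.5
C	74	453.032	242.896
C	75	465.08	244.083
C	76	477.024	246.055
C	77	488.814	248.804
C	78	500.399	252.318
C	79	511.729	256.582
C	80	522.756	261.579
C	81	533.433	267.285
C	82	543.713	273.678
C	83	553.554	280.73
C	84	562.912	288.41
C	85	571.747	296.685
C	86	580.023	305.521
C	87	587.703	314.879
C	88	594.755	324.72
C	89	601.147	335
C	90	606.854	345.677
C	91	611.85	356.704
C	92	616.115	368.034
C	93	619.629	379.618
C	94	622.378	391.408
C	95	624.35	403.353
C	96	625.537	415.4
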