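label	vertex	x	y
A	1	580	350
A	2	579.508	365.043
A	3	578.032	380.021
A	4	575.581	394.871
A	5	572.163	409.528
A	6	567.794	423.931
A	7	562.492	438.017
A	8	556.281	451.726
A	9	549.186	465
A	10	541.238	477.781
A	11	532.471	490.015
A	12	522.923	501.65
A	13	512.635	512.635
A	14	501.65	522.923
A	15	490.015	532.471
A	16	477.781	541.238
A	17	465	549.186
A	18	451.726	556.281
A	19	438.017	562.492
A	20	423.931	567.794
A	21	409.528	572.163
A	22	394.871	575.581
A	23	380.021	578.032
A	24	365.043	579.508
A	25	350	580
A	26	334.957	579.508
A	27	319.979	578.032
A	28	305.129	575.581
A	29	290.472	572.163
A	30	276.069	567.794
A	31	261.983	562.492
A	32	248.274	556.281
A	33	235	549.186
A	34	222.219	541.238
A	35	209.985	532.471
A	36	198.35	522.923
A	37	187.365	512.635
A	38	177.077	501.65
A	39	167.529	490.015
A	40	158.762	477.781
A	41	150.814	465
A	42	143.719	451.726
A	43	137.508	438.017
A	44	132.206	423.931
A	45	127.837	409.528
A	46	124.419	394.871
A	47	121.968	380.021
A	48	120.492	365.043
A	49	120	350
A	50	120.492	334.957
A	51	121.968	319.979
A	52	124.419	305.129
A	53	127.837	290.472
A	54	132.206	276.069
A	55	137.508	261.983
A	56	143.719	248.274
A	57	150.814	235
A	58	158.762	222.219
A	59	167.529	209.985
A	60	177.077	198.35
A	61	187.365	187.365
A	62	198.35	177.077
A	63	209.985	167.529
A	64	222.219	158.762
A	65	235	150.814
A	66	248.274	143.719
A	67	261.983	137.508
A	68	276.069	132.206
A	69	290.472	127.837
A	70	305.129	124.419
A	71	319.979	121.968
A	72	334.957	120.492
A	73	350	120
A	74	365.043	120.492
A	75	380.021	121.968
A	76	394.871	124.419
A	77	409.528	127.837
A	78	423.931	132.206
A	79	438.017	137.508
A	80	451.726	143.719
A	81	465	150.814
A	82	477.781	158.762
A	83	490.015	167.529
A	84	501.65	177.077
A	85	512.635	187.365
A	86	522.923	198.35
A	87	532.471	209.985
A	88	541.238	222.219
A	89	549.186	235
A	90	556.281	248.274
A	91	562.492	261.983
A	92	567.794	276.069
A	93	572.163	290.472
A	94	575.581	305.129
A	95	578.032	319.979
A	96	579.508	334.957
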