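ref_segment	query_segment	total_snps	snps_cds	total_indels	indels_cds
1	2	132	91	8	3
1	3	86	66	14	0
1	4	145	124	27	8
1	5	300	136	41	12
1	6	757	316	82	15
2	1	151	94	16	3
2	3	132	116	15	3
2	4	135	135	17	3
2	5	302	138	44	12
2	6	682	303	64	13
3	1	84	84	24	0
3	2	118	101	15	3
3	4	194	118	24	8
3	5	341	140	47	12
3	6	798	325	76	15
4	1	126	91	24	8
4	2	153	94	13	3
4	3	146	112	24	8
4	5	358	158	43	21
4	6	568	301	64	13
5	1	374	192	55	17
5	2	352	162	54	17
5	3	394	153	61	17
5	4	456	209	59	26
5	6	548	201	58	16
6	1	663	354	80	15
6	2	624	339	75	13
6	3	712	342	76	15
6	4	649	345	77	15
6	5	587	193	65	16
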