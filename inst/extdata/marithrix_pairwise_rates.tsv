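metric	ref_segment	query_segment	value
snps_per_100kbp	1	2	4.1
snps_per_100kbp	1	3	2.65
snps_per_100kbp	1	4	4.65
snps_per_100kbp	1	5	11.79
snps_per_100kbp	1	6	31.51
snps_per_100kbp	2	1	4.7
snps_per_100kbp	2	3	4.07
snps_per_100kbp	2	4	4.33
snps_per_100kbp	2	5	11.87
snps_per_100kbp	2	6	28.39
snps_per_100kbp	3	1	2.62
snps_per_100kbp	3	2	3.67
snps_per_100kbp	3	4	6.23
snps_per_100kbp	3	5	13.4
snps_per_100kbp	3	6	33.22
snps_per_100kbp	4	1	3.92
snps_per_100kbp	4	2	4.75
snps_per_100kbp	4	3	4.51
snps_per_100kbp	4	5	14.07
snps_per_100kbp	4	6	23.64
snps_per_100kbp	5	1	11.65
snps_per_100kbp	5	2	10.94
snps_per_100kbp	5	3	12.16
snps_per_100kbp	5	4	14.63
snps_per_100kbp	5	6	22.81
snps_per_100kbp	6	1	20.65
snps_per_100kbp	6	2	19.39
snps_per_100kbp	6	3	21.98
snps_per_100kbp	6	4	20.83
snps_per_100kbp	6	5	23.07
indels_per_100kbp	1	2	0.25
indels_per_100kbp	1	3	0.43
indels_per_100kbp	1	4	0.87
indels_per_100kbp	1	5	1.61
indels_per_100kbp	1	6	3.41
indels_per_100kbp	2	1	0.5
indels_per_100kbp	2	3	0.46
indels_per_100kbp	2	4	0.55
indels_per_100kbp	2	5	1.73
indels_per_100kbp	2	6	2.66
indels_per_100kbp	3	1	0.75
indels_per_100kbp	3	2	0.47
indels_per_100kbp	3	4	0.77
indels_per_100kbp	3	5	1.85
indels_per_100kbp	3	6	3.16
indels_per_100kbp	4	1	0.75
indels_per_100kbp	4	2	0.4
indels_per_100kbp	4	3	0.74
indels_per_100kbp	4	5	1.69
indels_per_100kbp	4	6	2.66
indels_per_100kbp	5	1	1.71
indels_per_100kbp	5	2	1.68
indels_per_100kbp	5	3	1.88
indels_per_100kbp	5	4	1.89
indels_per_100kbp	5	6	2.41
indels_per_100kbp	6	1	2.49
indels_per_100kbp	6	2	2.33
indels_per_100kbp	6	3	2.35
indels_per_100kbp	6	4	2.47
indels_per_100kbp	6	5	2.55
snps_cds_per_100kbp	1	2	3.2
snps_cds_per_100kbp	1	3	2.29
snps_cds_per_100kbp	1	4	4.5
snps_cds_per_100kbp	1	5	6.12
snps_cds_per_100kbp	1	6	15
snps_cds_per_100kbp	2	1	3.31
snps_cds_per_100kbp	2	3	4.02
snps_cds_per_100kbp	2	4	4.9
snps_cds_per_100kbp	2	5	6.21
snps_cds_per_100kbp	2	6	14.38
snps_cds_per_100kbp	3	1	2.96
snps_cds_per_100kbp	3	2	3.55
snps_cds_per_100kbp	3	4	4.28
snps_cds_per_100kbp	3	5	6.3
snps_cds_per_100kbp	3	6	15.43
snps_cds_per_100kbp	4	1	3.21
snps_cds_per_100kbp	4	2	3.31
snps_cds_per_100kbp	4	3	3.89
snps_cds_per_100kbp	4	5	7.11
snps_cds_per_100kbp	4	6	14.29
snps_cds_per_100kbp	5	1	6.77
snps_cds_per_100kbp	5	2	5.7
snps_cds_per_100kbp	5	3	5.31
snps_cds_per_100kbp	5	4	7.58
snps_cds_per_100kbp	5	6	9.54
snps_cds_per_100kbp	6	1	12.48
snps_cds_per_100kbp	6	2	11.92
snps_cds_per_100kbp	6	3	11.87
snps_cds_per_100kbp	6	4	12.51
snps_cds_per_100kbp	6	5	8.69
snps_ncds_per_100kbp	1	2	10.94
snps_ncds_per_100kbp	1	3	5.6
snps_ncds_per_100kbp	1	4	5.85
snps_ncds_per_100kbp	1	5	50.68
snps_ncds_per_100kbp	1	6	149.08
snps_ncds_per_100kbp	2	1	15.26
snps_ncds_per_100kbp	2	3	4.48
snps_ncds_per_100kbp	2	4	0
snps_ncds_per_100kbp	2	5	50.68
snps_ncds_per_100kbp	2	6	128.12
snps_ncds_per_100kbp	3	1	0
snps_ncds_per_100kbp	3	2	4.53
snps_ncds_per_100kbp	3	4	21.18
snps_ncds_per_100kbp	3	5	62.12
snps_ncds_per_100kbp	3	6	159.9
snps_ncds_per_100kbp	4	1	9.37
snps_ncds_per_100kbp	4	2	15.74
snps_ncds_per_100kbp	4	3	9.51
snps_ncds_per_100kbp	4	5	61.81
snps_ncds_per_100kbp	4	6	90.26
snps_ncds_per_100kbp	5	1	48.72
snps_ncds_per_100kbp	5	2	50.68
snps_ncds_per_100kbp	5	3	67.43
snps_ncds_per_100kbp	5	4	68.83
snps_ncds_per_100kbp	5	6	117.31
snps_ncds_per_100kbp	6	1	82.72
snps_ncds_per_100kbp	6	2	76.02
snps_ncds_per_100kbp	6	3	103.52
snps_ncds_per_100kbp	6	4	84.72
snps_ncds_per_100kbp	6	5	121.76
indels_cds_per_100kbp	1	2	0.12
indels_cds_per_100kbp	1	3	0
indels_cds_per_100kbp	1	4	0.34
indels_cds_per_100kbp	1	5	0.63
indels_cds_per_100kbp	1	6	0.82
indels_cds_per_100kbp	2	1	0.11
indels_cds_per_100kbp	2	3	0.1
indels_cds_per_100kbp	2	4	0.11
indels_cds_per_100kbp	2	5	0.54
indels_cds_per_100kbp	2	6	0.62
indels_cds_per_100kbp	3	1	0
indels_cds_per_100kbp	3	2	0.11
indels_cds_per_100kbp	3	4	0.29
indels_cds_per_100kbp	3	5	0.54
indels_cds_per_100kbp	3	6	0.71
indels_cds_per_100kbp	4	1	0.28
indels_cds_per_100kbp	4	2	0.11
indels_cds_per_100kbp	4	3	0.28
indels_cds_per_100kbp	4	5	0.95
indels_cds_per_100kbp	4	6	0.62
indels_cds_per_100kbp	5	1	0.6
indels_cds_per_100kbp	5	2	0.6
indels_cds_per_100kbp	5	3	0.59
indels_cds_per_100kbp	5	4	0.94
indels_cds_per_100kbp	5	6	0.76
indels_cds_per_100kbp	6	1	0.53
indels_cds_per_100kbp	6	2	0.46
indels_cds_per_100kbp	6	3	0.52
indels_cds_per_100kbp	6	4	0.54
indels_cds_per_100kbp	6	5	0.72
indels_ncds_per_100kbp	1	2	1.33
indels_ncds_per_100kbp	1	3	3.92
indels_ncds_per_100kbp	1	4	5.29
indels_ncds_per_100kbp	1	5	8.96
indels_ncds_per_100kbp	1	6	22.65
indels_ncds_per_100kbp	2	1	3.48
indels_ncds_per_100kbp	2	3	3.36
indels_ncds_per_100kbp	2	4	3.9
indels_ncds_per_100kbp	2	5	9.89
indels_ncds_per_100kbp	2	6	17.24
indels_ncds_per_100kbp	3	1	6.43
indels_ncds_per_100kbp	3	2	3.2
indels_ncds_per_100kbp	3	4	4.46
indels_ncds_per_100kbp	3	5	10.82
indels_ncds_per_100kbp	3	6	20.62
indels_ncds_per_100kbp	4	1	4.28
indels_ncds_per_100kbp	4	2	2.67
indels_ncds_per_100kbp	4	3	4.48
indels_ncds_per_100kbp	4	5	6.8
indels_ncds_per_100kbp	4	6	17.24
indels_ncds_per_100kbp	5	1	10.17
indels_ncds_per_100kbp	5	2	9.87
indels_ncds_per_100kbp	5	3	12.31
indels_ncds_per_100kbp	5	4	9.2
indels_ncds_per_100kbp	5	6	14.2
indels_ncds_per_100kbp	6	1	17.4
indels_ncds_per_100kbp	6	2	16.54
indels_ncds_per_100kbp	6	3	17.07
indels_ncds_per_100kbp	6	4	17.28
indels_ncds_per_100kbp	6	5	15.14
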