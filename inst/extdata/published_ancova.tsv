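snp	region	cohort	F	p	posthoc
rs10964536	9p21.3	CAMP	12.03	1.71e-09	4-1,5-1,4-3
rs10964536	9p21.3	GACRS	3.23	0.0121	5-1
rs28892326	7q33	CAMP	11.92	2.11e-09	4-1,5-1
rs28892326	7q33	GACRS	3.04	0.0166	5-2
rs2823880	21q21.1	CAMP	11.43	5.09e-09	4-1,5-1
rs2823880	21q21.1	GACRS	5.12	0.0004	4-1,4-2,4-3
rs10086065	8p23.1	CAMP	11.42	5.23e-09	4-1,5-1
rs10086065	8p23.1	GACRS	2.53	0.0390	4-1
rs12448208	16q12.1	CAMP	10.35	3.59e-08	2-1,4-1
rs12448208	16q12.1	GACRS	2.81	0.0246	5-1
rs2754324	9p22.2	CAMP	10.29	4.00e-08	4-1,4-3
rs2754324	9p22.2	GACRS	2.73	0.0282	5-3
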