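snp	endophenotype	cohort	or	p
rs10964536	1	CAMP	1.97	0.0010
rs10964536	1	GACRS	1.37	0.749
rs10964536	2	CAMP	0.97	0.841
rs10964536	2	GACRS	1.04	0.273
rs10964536	3	CAMP	1.30	0.129
rs10964536	3	GACRS	0.86	0.029
rs10964536	4	CAMP	0.65	0.0028
rs10964536	4	GACRS	1.21	0.168
rs10964536	5	CAMP	0.78	0.088
rs10964536	5	GACRS	0.70	0.0053
rs28892326	1	CAMP	3.44	0.0007
rs28892326	1	GACRS	1.61	0.0304
rs28892326	2	CAMP	1.00	0.995
rs28892326	2	GACRS	1.86	0.541
rs28892326	3	CAMP	1.05	0.815
rs28892326	3	GACRS	0.87	0.077
rs28892326	4	CAMP	0.75	0.098
rs28892326	4	GACRS	0.81	0.323
rs28892326	5	CAMP	0.68	0.021
rs28892326	5	GACRS	0.62	0.019
rs2823880	1	CAMP	1.95	0.0031
rs2823880	1	GACRS	1.47	0.149
rs2823880	2	CAMP	1.01	0.952
rs2823880	2	GACRS	1.45	0.100
rs2823880	3	CAMP	1.10	0.590
rs2823880	3	GACRS	1.55	0.136
rs2823880	4	CAMP	0.75	0.054
rs2823880	4	GACRS	0.44	4e-05
rs2823880	5	CAMP	0.77	0.085
rs2823880	5	GACRS	0.93	0.733
rs10086065	1	CAMP	2.24	0.0016
rs10086065	1	GACRS	1.44	0.374
rs10086065	2	CAMP	0.90	0.550
rs10086065	2	GACRS	1.22	0.818
rs10086065	3	CAMP	1.10	0.581
rs10086065	3	GACRS	1.05	0.117
rs10086065	4	CAMP	0.70	0.021
rs10086065	4	GACRS	0.57	0.0029
rs10086065	5	CAMP	0.86	0.321
rs10086065	5	GACRS	1.07	0.746
rs12448208	1	CAMP	2.56	0.0022
rs12448208	1	GACRS	0.60	0.183
rs12448208	2	CAMP	0.66	0.017
rs12448208	2	GACRS	1.35	0.373
rs12448208	3	CAMP	1.37	0.160
rs12448208	3	GACRS	1.22	0.0068
rs12448208	4	CAMP	0.63	0.0083
rs12448208	4	GACRS	0.81	0.279
rs12448208	5	CAMP	1.06	0.755
rs12448208	5	GACRS	1.44	0.111
rs2754324	1	CAMP	1.56	0.0288
rs2754324	1	GACRS	0.93	0.558
rs2754324	2	CAMP	1.05	0.798
rs2754324	2	GACRS	1.16	0.0162
rs2754324	3	CAMP	1.41	0.077
rs2754324	3	GACRS	2.05	0.762
rs2754324	4	CAMP	0.56	0.0001
rs2754324	4	GACRS	0.98	0.946
rs2754324	5	CAMP	0.96	0.798
rs2754324	5	GACRS	0.58	0.0088
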