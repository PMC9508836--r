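dataset	tool	calls	tp	fp	tn	fn	reported_sensitivity	reported_specificity	reported_precision	reported_accuracy
giab_wgs	cnn_caller	1233	1198	35	640	125	90.55	94.81	97.16	91.99
giab_wgs	denovogear_0.5	1346	1063	283	392	260	80.35	58.07	78.97	72.82
giab_wgs	denovogear_0.9	1161	1047	114	561	276	79.14	83.11	90.18	80.48
giab_wgs	deeptrio_wgs_bqsr	210	176	34	641	1147	13.3	94.96	83.81	40.89
giab_wgs	deeptrio_wgs_nobqsr	268	240	28	647	1083	18.14	95.85	89.55	44.39
giab_wgs	deeptrio_unfiltered_bqsr	1207	1127	80	595	196	85.19	88.15	93.37	86.19
giab_wgs	deeptrio_unfiltered_nobqsr	1222	1129	93	582	194	85.34	86.22	92.39	85.64
giab_wgs	gatk	1338	1171	167	508	152	88.51	75.26	87.52	84.03
giab_wgs	gatk_hc	1257	1149	108	567	174	86.85	84.0	91.41	85.89
giab_wgs	rule_based	1293	1195	98	577	128	90.33	85.48	92.42	88.69
wes_trios	cnn_caller	75	24	51	2488	0	100.0	97.99	32.0	98.01
wes_trios	gatk_hc	103	20	83	2456	4	83.33	96.73	19.42	96.61
wes_trios	gatk	147	20	127	2412	4	83.33	95.0	13.61	94.89
wes_trios	denovogear_0.9	599	19	580	1959	5	79.17	77.16	3.17	77.18
wes_trios	rule_based	85	20	65	2474	4	83.33	97.44	23.53	97.31
wgs_trios	cnn_caller	2335	509	1826	23557	113	81.83	92.81	21.8	92.54
wgs_trios	gatk_hc	5562	471	5091	20292	151	75.72	79.94	8.47	79.84
wgs_trios	gatk	8353	475	7878	17505	147	76.37	68.96	5.69	69.14
wgs_trios	deeptrio_unfiltered	14554	457	14097	11286	165	73.47	44.46	3.14	45.16
wgs_trios	deeptrio_wgs	5792	98	5694	19689	524	15.76	77.57	1.69	76.09
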