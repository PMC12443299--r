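level	soc	term	a	ror	ror_lo	ror_hi	prr	prr_lo	prr_hi	chi2	ic	ic025	ebgm	ebgm05
PT	reproductive system and breast disorders	endometriosis male	7	13615.84	1675.1	110674.81	13612.3	1671.59	110849.54	11909.01	10.73	9.36	1702.41	294.87
PT	congenital, familial and genetic disorders	5-alpha-reductase deficiency	5	1620.81	494.62	5311.25	1620.51	490.24	5356.66	4414.13	9.79	8.37	884.37	327.59
PT	endocrine disorders	secondary sexual characteristics absence	3	729.31	193.47	2749.24	729.23	192.33	2764.98	1586.69	9.05	7.42	530.62	174.81
PT	congenital, familial and genetic disorders	bulbospinal muscular atrophy congenital	6	402.42	167.06	969.36	402.33	166.55	971.92	1990.25	8.38	7.21	333.53	159.83
PT	investigations	blood aldosterone abnormal	3	388.97	112.6	1343.67	388.92	113.13	1336.99	967.31	8.34	6.79	324.27	114.93
PT	neoplasms benign, malignant and unspecified (incl cysts and polyps)	double hit lymphoma	5	243.12	95.95	616.06	243.08	96.76	610.69	1071.47	7.76	6.53	216.18	99.3
PT	reproductive system and breast disorders	female sexual arousal disorder	8	207.49	100.08	430.16	207.43	100.44	428.37	1485.04	7.55	6.56	187.53	101.89
PT	congenital, familial and genetic disorders	hypocalvaria	10	206.95	107.82	397.24	206.87	108.34	395.0	1851.79	7.55	6.65	187.08	108.41
PT	psychiatric disorders	gender dysphoria	7	206.3	94.65	449.68	206.25	94.17	451.73	1292.66	7.54	6.49	186.57	97.2
PT	congenital, familial and genetic disorders	genitalia external ambiguous	14	180.39	104.31	311.94	180.3	104.15	312.13	2284.42	7.37	6.6	165.08	104.39
PT	congenital, familial and genetic disorders	congenital musculoskeletal disorder	3	132.6	41.17	427.08	132.59	40.91	429.77	366.78	6.96	5.48	124.19	46.67
PT	reproductive system and breast disorders	asthenospermia	4	131.86	47.89	363.02	131.84	47.58	365.33	486.41	6.95	5.64	123.53	52.94
PT	investigations	blood aldosterone increased	8	103.74	50.94	211.29	103.71	51.21	210.02	772.58	6.62	5.65	98.51	54.33
PT	blood and lymphatic system disorders	spur cell anaemia	3	97.24	30.5	310.07	97.23	30.59	309.04	272.12	6.53	5.08	92.65	35.11
PT	investigations	electrocardiogram t wave peaked	16	94.05	56.94	155.36	94.0	56.47	156.47	1404.29	6.49	5.78	89.71	58.95
PT	investigations	electrocardiogram t wave amplitude increased	4	93.73	34.36	255.65	93.72	34.49	254.66	350.04	6.48	5.18	89.45	38.63
PT	metabolism and nutrition disorders	hyperkalaemia	1308	90.35	85.37	95.62	86.01	81.1	91.22	105303.2	6.36	6.28	82.41	78.59
PT	reproductive system and breast disorders	oligospermia	4	85.49	31.41	232.71	85.48	31.46	232.27	319.9	6.36	5.06	81.92	35.44
PT	skin and subcutaneous tissue disorders	urticaria cholinergic	3	84.56	26.61	268.66	84.55	26.6	268.74	237.36	6.34	4.89	81.07	30.82
PT	skin and subcutaneous tissue disorders	acute cutaneous lupus erythematosus	5	81.04	33.12	198.27	81.03	32.89	199.62	379.38	6.28	5.1	77.82	36.81
PT	injury, poisoning and procedural complications	therapeutic drug monitoring analysis not performed	11	80.15	43.85	146.5	80.12	43.64	147.1	825.4	6.27	5.43	76.98	46.48
PT	reproductive system and breast disorders	spermatogenesis abnormal	3	72.93	23.03	230.95	72.92	22.94	231.77	205.12	6.14	4.69	70.32	26.81
PT	neoplasms benign, malignant and unspecified (incl cysts and polyps)	hormone receptor positive breast cancer	7	69.12	32.52	146.9	69.1	32.81	145.53	453.67	6.06	5.04	66.76	35.53
PT	metabolism and nutrition disorders	hypoosmolar state	4	67.65	24.96	183.33	67.64	24.89	183.79	253.79	6.03	4.74	65.4	28.4
PT	congenital, familial and genetic disorders	angiotensin converting enzyme inhibitor foetopathy	3	66.3	20.98	209.56	66.29	20.86	210.7	186.57	6.0	4.56	64.14	24.49
PT	investigations	renin increased	8	65.66	32.45	132.84	65.64	32.41	132.93	492.62	5.99	5.03	63.53	35.23
PT	metabolism and nutrition disorders	neonatal hyponatraemia	3	52.56	16.7	165.48	52.56	16.54	167.06	147.74	5.68	4.24	51.2	19.61
PT	investigations	blood pressure orthostatic	4	51.86	19.21	140.0	51.86	19.09	140.91	194.32	5.66	4.37	50.54	22.02
PT	congenital, familial and genetic disorders	gastrointestinal malformation	5	50.65	20.84	123.09	50.64	20.96	122.33	237.13	5.63	4.45	49.38	23.49
PT	reproductive system and breast disorders	nipple pain	42	46.19	34.0	62.74	46.12	33.71	63.11	1810.96	5.49	5.06	45.07	34.88
SOC	metabolism and nutrition disorders	metabolism and nutrition disorders	3234	6.06	5.84	6.28	5.45	5.24	5.67	11982.07	2.44	2.39	5.44	5.27
SOC	reproductive system and breast disorders	reproductive system and breast disorders	913	4.11	3.85	4.39	4.01	3.78	4.25	2073.34	2.0	1.9	4.0	3.79
SOC	renal and urinary disorders	renal and urinary disorders	1701	3.5	3.33	3.68	3.34	3.21	3.47	2839.46	1.74	1.67	3.34	3.2
SOC	cardiac disorders	cardiac disorders	1551	2.17	2.06	2.28	2.1	2.02	2.18	919.63	1.07	1.0	2.1	2.01
SOC	endocrine disorders	endocrine disorders	143	2.04	1.73	2.41	2.04	1.74	2.39	75.52	1.03	0.79	2.04	1.77
SOC	congenital, familial and genetic disorders	congenital, familial and genetic disorders	160	1.88	1.61	2.19	1.87	1.6	2.19	64.96	0.9	0.68	1.87	1.64
SOC	vascular disorders	vascular disorders	942	1.59	1.49	1.7	1.57	1.48	1.67	201.57	0.65	0.56	1.57	1.49
SOC	hepatobiliary disorders	hepatobiliary disorders	344	1.36	1.22	1.52	1.36	1.23	1.5	32.68	0.44	0.29	1.36	1.24
SOC	immune system disorders	immune system disorders	415	1.36	1.23	1.49	1.35	1.22	1.49	38.26	0.43	0.29	1.35	1.25
SOC	investigations	investigations	2188	1.3	1.24	1.36	1.27	1.22	1.32	137.95	0.35	0.29	1.27	1.23
SOC	ear and labyrinth disorders	ear and labyrinth disorders	141	1.18	1.0	1.39	1.18	1.01	1.38	3.92	0.24	0.0	1.18	1.03
SOC	skin and subcutaneous tissue disorders	skin and subcutaneous tissue disorders	1543	1.04	0.99	1.1	1.04	1.0	1.08	2.27	0.05	-0.02	1.04	0.99
SOC	blood and lymphatic system disorders	blood and lymphatic system disorders	436	0.92	0.84	1.01	0.92	0.83	1.01	2.79	-0.11	-0.25	0.92	0.85
SOC	nervous system disorders	nervous system disorders	2021	0.85	0.81	0.89	0.86	0.83	0.89	50.52	-0.22	-0.28	0.86	0.83
SOC	gastrointestinal disorders	gastrointestinal disorders	1991	0.83	0.79	0.87	0.84	0.81	0.87	65.88	-0.25	-0.32	0.84	0.81
SOC	respiratory, thoracic and mediastinal disorders	respiratory, thoracic and mediastinal disorders	1022	0.76	0.72	0.81	0.77	0.73	0.82	71.28	-0.37	-0.46	0.77	0.73
SOC	pregnancy, puerperium and perinatal conditions	pregnancy, puerperium and perinatal conditions	86	0.72	0.58	0.89	0.72	0.58	0.89	9.35	-0.47	-0.78	0.72	0.6
SOC	general disorders and administration site conditions	general disorders and administration site conditions	3555	0.7	0.67	0.72	0.74	0.71	0.77	403.36	-0.44	-0.49	0.74	0.72
SOC	injury, poisoning and procedural complications	injury, poisoning and procedural complications	1590	0.59	0.56	0.62	0.62	0.6	0.64	421.82	-0.7	-0.77	0.62	0.59
SOC	psychiatric disorders	psychiatric disorders	952	0.59	0.55	0.63	0.6	0.57	0.64	265.47	-0.73	-0.82	0.6	0.57
SOC	musculoskeletal and connective tissue disorders	musculoskeletal and connective tissue disorders	778	0.52	0.48	0.56	0.53	0.49	0.57	339.33	-0.91	-1.01	0.53	0.5
SOC	eye disorders	eye disorders	285	0.51	0.45	0.57	0.51	0.45	0.57	134.49	-0.96	-1.13	0.51	0.47
SOC	infections and infestations	infections and infestations	531	0.35	0.32	0.38	0.36	0.33	0.39	622.83	-1.46	-1.58	0.36	0.34
SOC	neoplasms benign, malignant and unspecified(incl cysts and polyps)	neoplasms benign, malignant and unspecified(incl cysts and polyps)	259	0.35	0.31	0.39	0.35	0.31	0.39	317.34	-1.51	-1.68	0.35	0.32
SOC	surgical and medical procedures	surgical and medical procedures	124	0.33	0.28	0.39	0.33	0.28	0.39	169.5	-1.59	-1.85	0.33	0.29
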