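species	annotation	tpm_2nd	tpm_4th	r_4th_2nd	tpm_m	tpm_f	r_f_m	tpm_nymphs	tpm_adults	r_adults_nymphs	id
hbug	Acetoacetyl-CoA thiolase	176.92	131.53	-0.43	211.58	344.29	0.70	154.39	267.85	0.79	HBug_USDA-ARS_IIBBL.267134
hbug	Acetoacetyl-CoA thiolase	41.01	28.64	-0.52	21.84	33.13	0.60	34.61	26.66	-0.38	HBug_USDA-ARS_IIBBL.43170
hbug	HMG-CoA reductase	15.83	12.42	-0.35	29.97	22.95	-0.39	14.10	27.05	0.94	HBug_USDA-ARS_IIBBL.421664
hbug	HMG-CoA synthase	0.53	0.60	0.18	0.27	0.45	0.74	0.57	0.35	-0.70	HBug_USDA-ARS_IIBBL.375421
hbug	Mevalonate kinase	0.11	0.28	1.35	0.05	0.33	2.72	0.22	0.13	-0.76	HBug_USDA-ARS_IIBBL.227208
hbug	Phosphomevalonate kinase	4.51	2.76	-0.71	6.08	3.08	-0.98	3.59	4.76	0.41	HBug_USDA-ARS_IIBBL.270718
hbug	Diphosphomevalonate decarboxylase	0.05	0.12	1.26	0.13	0.11	-0.24	0.09	0.14	0.64	HBug_USDA-ARS_IIBBL.428020
hbug	IDP Isomerase	20.22	10.48	-0.95	15.04	13.73	-0.13	15.32	14.53	-0.08	HBug_USDA-ARS_IIBBL.92242
hbug	FDP Synthase	3.44	0.41	-3.07	46.44	3.51	-3.73	1.92	28.48	3.89	HBug_USDA-ARS_IIBBL.420512
hbug	FDP Synthase	25.04	23.37	-0.10	32.47	31.56	-0.04	23.79	32.17	0.44	HBug_USDA-ARS_IIBBL.414919
hbug	Farnesol dehydrogenase	0.16	0.15	-0.09	0.00	0.00	undefined	0.16	0.00	-inf	HBug_USDA-ARS_IIBBL.414590
hbug	Farnesol dehydrogenase	0.00	0.13	+inf	0.07	0.45	2.68	0.03	0.15	2.32	HBug_USDA-ARS_IIBBL.328207
hbug	Farnesol dehydrogenase	13.27	9.88	-0.43	7.78	7.54	-0.05	11.57	7.81	-0.57	HBug_USDA-ARS_IIBBL.376500
hbug	Farnesal dehydrogenase	0.29	0.20	-0.54	8.14	12.84	0.66	0.24	10.14	5.40	HBug_USDA-ARS_IIBBL.14716
hbug	Farnesal dehydrogenase	3.29	9.14	1.47	4.99	5.77	0.21	6.24	5.30	-0.24	HBug_USDA-ARS_IIBBL.79640
hbug	Juvenile hormone acid methyltransferase	0.04	0.00	-inf	0.12	0.03	-2.00	0.00	0.09	+inf	HBug_USDA-ARS_IIBBL.519494
hbug	Juvenile hormone acid methyltransferase	3.04	10.78	1.83	4.97	64.51	3.70	6.87	30.65	2.16	HBug_USDA-ARS_IIBBL.485486
hbug	Juvenile hormone acid methyltransferase	0.03	1.22	5.35	0.09	0.28	1.64	0.68	0.17	-2.00	HBug_USDA-ARS_IIBBL.346622
hbug	Methyl farnesoate epoxidase	0.39	0.12	-1.70	0.18	0.14	-0.36	0.25	0.17	-0.56	HBug_USDA-ARS_IIBBL.517163
bmsb	Acetoacetyl-CoA thiolase	175.06	168.71	-0.05	793.94	942.05	0.25	171.71	864.84	2.33	XP_014294739.1
bmsb	Acetoacetyl-CoA thiolase	70.48	65.24	-0.11	147.12	185.97	0.34	67.72	165.71	1.29	XP_014275331.1
bmsb	HMG-CoA reductase	18.12	21.68	0.26	44.27	25.96	-0.77	20.00	35.52	0.83	XP_014280269.1
bmsb	HMG-CoA synthase	0.00	0.00	undefined	0.44	1.40	1.67	0.00	1.28	+inf	XP_014277503.1
bmsb	Mevalonate kinase	8.00	8.54	0.09	12.13	7.82	-0.63	8.29	10.07	0.28	XP_014272243.1
bmsb	Phosphomevalonate kinase	5.97	4.46	-0.42	7.02	4.80	-0.55	5.17	5.96	0.21	XP_014271961.1
bmsb	Diphosphomevalonate decarboxylase	3.96	3.44	-0.20	4.90	3.98	-0.30	3.72	4.46	0.26	XP_014290216.1
bmsb	IDP Isomerase	13.51	10.56	-0.36	11.89	14.15	0.25	11.96	12.97	0.12	XP_014271459.1
bmsb	FDP Synthase	3.62	8.08	1.16	15.70	18.66	0.25	5.97	17.12	1.52	XP_014276183.1
bmsb	FDP Synthase	12.52	14.96	0.26	13.13	15.78	0.27	13.80	14.40	0.06	XP_014276401.1
bmsb	FDP synthase	0.04	0.16	2.00	0.80	0.04	-4.32	0.10	0.44	2.14	XP_014289203.1
bmsb	FDP synthase	0.29	0.29	0.00	0.35	0.22	-0.67	0.29	0.28	-0.05	XP_014289225.1
bmsb	Farnesol dehydrogenase	204.63	77.01	-1.41	35.70	46.26	0.37	137.30	40.68	-1.75	XP_014286519.1
bmsb	Farnesol dehydrogenase	78.56	47.27	-0.73	43.79	43.94	0.00	62.05	43.86	-0.50	XP_014286524.1
bmsb	Farnesol dehydrogenase	107.93	53.10	-1.02	44.15	27.32	-0.69	79.01	36.10	-1.13	XP_014286525.1
bmsb	Farnesal dehydrogenase	28.66	94.12	1.72	35.72	49.72	0.48	63.19	42.42	-0.57	XP_014272618.1
bmsb	Farnesal dehydrogenase	49.42	54.55	0.14	57.72	65.03	0.17	52.13	61.22	0.23	XP_014292700.1
bmsb	Juvenile hormone acid methyltransferase	0.13	0.06	-1.12	0.22	34.99	7.31	0.09	16.85	7.55	XP_014293044.1
bmsb	Juvenile hormone acid methyltransferase	46.90	45.31	-0.05	22.24	79.28	1.83	46.06	49.52	0.10	XP_014290953.1
bmsb	Juvenile hormone acid methyltransferase	0.38	0.34	-0.16	0.79	0.18	-2.13	0.36	0.50	0.47	XP_014283772.1
bmsb	Methyl farnesoate epoxidase	1.15	0.59	-0.96	0.16	0.26	0.70	0.86	0.21	-2.03	XP_014283057.1
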