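contrast	log2fc	direction	tpm_num	tpm_den	gene
2nd:4th	5.1284	up	253.24	7.24	adult-specific cuticular protein ACP-20-like
2nd:4th	4.6366	up	1055.89	42.45	uncharacterized protein LOC106688964
2nd:4th	3.6726	up	366.36	28.73	tubulin beta-1 chain
2nd:4th	3.5047	up	380.01	33.48	protein takeout-like
2nd:4th	3.3727	up	192.25	18.56	GTP cyclohydrolase 1 isoform X1
2nd:4th	5.3563	down	8.17	334.68	heat shock 70 kDa protein cognate 4
2nd:4th	5.3279	down	7.17	287.99	acyl-CoA Delta(11) desaturase-like isoform X1
2nd:4th	5.2056	down	6.33	233.59	uncharacterized protein LOC106679388
2nd:4th	4.7751	down	9.21	252.18	lysosomal alpha-mannosidase
2nd:4th	4.6475	down	6.05	151.63	uncharacterized protein LOC106683993
female:male	4.1357	up	375.11	21.34	heat shock 70 kDa protein cognate 4
female:male	3.5908	up	104.22	8.65	JH acid O-methyltransferase-like isoform X1
female:male	2.8439	up	88.45	12.32	uncharacterized protein LOC106679932
female:male	2.7760	up	124.18	18.13	troponin C, isoform 1-like
female:male	2.7262	up	34.21	5.17	adult-specific cuticular protein ACP-20-like
female:male	3.9320	down	570.39	8706.01	putative odorant-binding protein 4
female:male	2.7080	down	5.58	36.46	E3 ubiquitin-protein ligase TRIM37-like isoform X2
female:male	2.2543	down	6.29	30.01	exocyst complex component 7
female:male	1.9412	down	6.51	25.00	DDB1- and CUL4-associated factor 6-like
female:male	1.9045	down	7.18	26.88	exosome complex component CSL4
adults:nymphs	3.8701	up	5288.23	361.66	putative odorant-binding protein 4
adults:nymphs	3.7040	up	105.04	8.06	inositol monophosphatase 2-like
adults:nymphs	3.4889	up	98.80	8.80	uncharacterized protein LOC106686819
adults:nymphs	3.4091	up	78.93	7.43	uncharacterized protein LOC106691169
adults:nymphs	3.0628	up	264.22	31.62	NADP-dependent malic enzyme-like isoform X3
adults:nymphs	6.0853	down	44.80	3041.89	uncharacterized protein LOC106688633
adults:nymphs	4.3486	down	5.41	110.22	pro-resilin-like
adults:nymphs	3.7376	down	13.83	184.48	probable antibacterial peptide
adults:nymphs	3.6876	down	9.00	115.96	cuticle protein 18.6, isoform B
adults:nymphs	3.2451	down	11.07	104.96	GTP cyclohydrolase 1 isoform X1
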