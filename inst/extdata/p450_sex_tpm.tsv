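male	female	abs_log2_mf	direction	put_id	best_hit
0.03	18.87	9.2969	-	472510	XP_014270541.1 (CYP4GZ4)
0.07	24.35	8.4424	-	473495	XP_014286441.1 (CYP6LT5)
0.40	72.44	7.5006	-	419699	XP_014273208.1 (CYP6LT7)
0.06	8.73	7.1849	-	103772	XP_014286439.1 (CYP6LT3)
0.27	19.68	6.1876	-	103769	XP_014286439.1 (CYP6LT3)
6.35	0.00	undefined	+	478727	XP_014293876.1 (CYP307B1)
4.71	0.00	undefined	+	173857	XP_014285590.1 (CYP3226B1)
9.95	0.01	9.9586	+	298833	XP_014293876.1 (CYP307B1)
4.30	0.07	5.9408	+	137898	XP_014288222.1 (CYP3227B4)
3.26	0.15	4.4418	+	521147	XP_014276563.1 (CYP3225B3)
5.85	0.61	3.2616	+	428429	XP_014279285.1 (CYP302A1)
38.09	6.24	2.6098	+	103771	XP_014286439.1 (CYP6LT3)
21.99	6.92	1.6680	+	504543	XP_014284935.1 (CYP4HB7)
15.69	5.20	1.5933	+	456532	XP_014285589.1 (CYP3226B1)
25.99	8.88	1.5493	+	486339	XP_014285590.1 (CYP3226B1)
14.45	5.10	1.5025	+	316472	XP_014274999.1 (CYP3224A2)
15.06	5.51	1.4506	+	165088	XP_014271425.1 (CYP6LU1)
13.48	6.26	1.1066	+	212119	XP_014284933.1 (CYP4HB6)
7.51	15.33	1.0295	-	504542	XP_014284935.1 (CYP4HB7)
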