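# synthetic generic-numbering reference table (not a database snapshot)
# sequence: FAYLGESMDDEHGGGGGRMFDCKTEMERSGGGGGDGNEKNPHWCECGGGGGRSQMMNLFGGGGGEVWDNPGFWHLAGGGGGGDCNLSIVFHVVHRRMGGGGGGKYFTLPFYRERGGGGGHLQFSITQFALATGGGGGGVIVVALQGKCAE
generic_label	segment	ref_seq_index	ref_aa
1.30	TM1	1	F
1.31	TM1	2	A
1.32	TM1	3	Y
1.33	TM1	4	L
1.34	TM1	5	G
1.35	TM1	6	E
1.36	TM1	7	S
1.37	TM1	8	M
1.38	TM1	9	D
1.39	TM1	10	D
1.40	TM1	11	E
1.41	TM1	12	H
2.35	TM2	18	R
2.36	TM2	19	M
2.37	TM2	20	F
2.38	TM2	21	D
2.39	TM2	22	C
2.40	TM2	23	K
2.41	TM2	24	T
2.42	TM2	25	E
2.43	TM2	26	M
2.44	TM2	27	E
2.45	TM2	28	R
2.46	TM2	29	S
3.44	TM3	35	D
3.45	TM3	36	G
3.46	TM3	37	N
3.47	TM3	38	E
3.48	TM3	39	K
3.49	TM3	40	N
3.50	TM3	41	P
3.51	TM3	42	H
3.52	TM3	43	W
3.53	TM3	44	C
3.54	TM3	45	E
3.55	TM3	46	C
34.50	ICL2	52	R
34.51	ICL2	53	S
34.52	ICL2	54	Q
34.53	ICL2	55	M
34.54	ICL2	56	M
34.55	ICL2	57	N
34.56	ICL2	58	L
34.57	ICL2	59	F
4.40	TM4	65	E
4.41	TM4	66	V
4.42	TM4	67	W
4.43	TM4	68	D
4.44	TM4	69	N
4.45	TM4	70	P
4.46	TM4	71	G
4.47	TM4	72	F
4.48	TM4	73	W
4.49	TM4	74	H
4.50	TM4	75	L
4.51	TM4	76	A
5.60	TM5	82	G
5.61	TM5	83	D
5.62	TM5	84	C
5.63	TM5	85	N
5.64	TM5	86	L
5.65	TM5	87	S
5.66	TM5	88	I
5.67	TM5	89	V
5.68	TM5	90	F
5.69	TM5	91	H
5.70	TM5	92	V
5.71	TM5	93	V
5.72	TM5	94	H
5.73	TM5	95	R
5.74	TM5	96	R
5.75	TM5	97	M
6.28	TM6	103	G
6.29	TM6	104	K
6.30	TM6	105	Y
6.31	TM6	106	F
6.32	TM6	107	T
6.33	TM6	108	L
6.34	TM6	109	P
6.35	TM6	110	F
6.36	TM6	111	Y
6.37	TM6	112	R
6.38	TM6	113	E
6.39	TM6	114	R
7.47	TM7	120	H
7.48	TM7	121	L
7.49	TM7	122	Q
7.50	TM7	123	F
7.51	TM7	124	S
7.52	TM7	125	I
7.53	TM7	126	T
7.54	TM7	127	Q
7.55	TM7	128	F
7.56	TM7	129	A
7.57	TM7	130	L
7.58	TM7	131	A
7.59	TM7	132	T
7.60	TM7	133	G
8.47	H8	139	V
8.48	H8	140	I
8.49	H8	141	V
8.50	H8	142	V
8.51	H8	143	A
8.52	H8	144	L
8.53	H8	145	Q
8.54	H8	146	G
8.55	H8	147	K
8.56	H8	148	C
8.57	H8	149	A
8.58	H8	150	E
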