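# synthetic generic-numbering reference table (not a database snapshot)
# sequence: ELDGGGGGKHLGGGGGVTVNYVFMNFHQCVCSAMPESSWWAR
generic_label	segment	ref_seq_index	ref_aa
S1.01	S1	1	E
S1.02	S1	2	L
S1.03	S1	3	D
S3.01	S3	9	K
S3.02	S3	10	H
S3.03	S3	11	L
H5.01	H5	17	V
H5.02	H5	18	T
H5.03	H5	19	V
H5.04	H5	20	N
H5.05	H5	21	Y
H5.06	H5	22	V
H5.07	H5	23	F
H5.08	H5	24	M
H5.09	H5	25	N
H5.10	H5	26	F
H5.11	H5	27	H
H5.12	H5	28	Q
H5.13	H5	29	C
H5.14	H5	30	V
H5.15	H5	31	C
H5.16	H5	32	S
H5.17	H5	33	A
H5.18	H5	34	M
H5.19	H5	35	P
H5.20	H5	36	E
H5.21	H5	37	S
H5.22	H5	38	S
H5.23	H5	39	W
H5.24	H5	40	W
H5.25	H5	41	A
H5.26	H5	42	R
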