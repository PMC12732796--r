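# synthetic generic-numbering reference table (not a database snapshot)
# sequence: DHHGGGGGIHMGGGGGHAMWMHPCQPNEIAKYKHPQQRWVNY
generic_label	segment	ref_seq_index	ref_aa
S1.01	S1	1	D
S1.02	S1	2	H
S1.03	S1	3	H
S3.01	S3	9	I
S3.02	S3	10	H
S3.03	S3	11	M
H5.01	H5	17	H
H5.02	H5	18	A
H5.03	H5	19	M
H5.04	H5	20	W
H5.05	H5	21	M
H5.06	H5	22	H
H5.07	H5	23	P
H5.08	H5	24	C
H5.09	H5	25	Q
H5.10	H5	26	P
H5.11	H5	27	N
H5.12	H5	28	E
H5.13	H5	29	I
H5.14	H5	30	A
H5.15	H5	31	K
H5.16	H5	32	Y
H5.17	H5	33	K
H5.18	H5	34	H
H5.19	H5	35	P
H5.20	H5	36	Q
H5.21	H5	37	Q
H5.22	H5	38	R
H5.23	H5	39	W
H5.24	H5	40	V
H5.25	H5	41	N
H5.26	H5	42	Y
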