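# synthetic Galpha subfamily H5 alignment with planted conserved columns
family	H5.01	H5.02	H5.03	H5.04	H5.05	H5.06	H5.07	H5.08	H5.09	H5.10	H5.11	H5.12	H5.13	H5.14	H5.15	H5.16	H5.17	H5.18	H5.19	H5.20	H5.21	H5.22	H5.23	H5.24	H5.25	H5.26
Gs	L	W	I	R	V	G	T	Q	E	R	Q	D	V	I	G	N	M	K	I	M	C	T	M	P	H	W
Gi1	L	H	I	I	R	C	T	Q	D	K	I	K	V	G	E	V	S	K	V	M	Y	S	P	E	H	E
Gi2	L	C	I	N	G	E	T	Q	P	C	S	S	V	L	S	A	C	Y	D	M	C	K	N	L	H	L
Go	L	R	I	W	S	G	T	Q	K	N	V	I	V	P	T	T	K	Q	V	M	V	R	C	H	H	T
Gq	L	I	I	Y	E	M	T	Q	I	I	F	S	V	H	M	A	T	M	P	M	I	M	Y	N	H	G
G12	L	D	I	I	M	I	T	Q	P	L	G	V	V	N	P	N	I	Y	V	M	F	I	A	P	H	N
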