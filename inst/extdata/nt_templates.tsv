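resname	atom	x	y	z
A	C1'	10.1244	-1.1477	0.2623
A	C2'	9.6909	-0.1482	1.2359
A	C3'	8.9291	0.897	0.393
A	C4'	9.671	0.8393	-0.8998
A	O4'	10.2132	-0.499	-1.0314
A	O2'	10.4744	0.0556	2.3904
A	O3'	7.6651	1.506	0.6116
A	C5'	8.3768	0.786	-1.6758
A	O5'	7.73	-0.4837	-1.4681
A	P	7.2122	-1.3568	-2.7049
A	OP1	8.353	-1.5705	-3.6233
A	OP2	6.1289	-0.6034	-3.3749
A	N9	11.1592	-2.1084	0.7059
A	C8	11.4	-2.4975	2.0079
A	N7	12.4422	-3.4019	1.9968
A	C5	12.8456	-3.5717	0.6881
A	C4	12.0527	-2.7723	-0.1097
A	N3	12.2467	-2.7522	-1.4759
A	C2	13.2336	-3.5315	-2.0442
A	N1	14.0266	-4.3309	-1.2464
A	C6	13.8326	-4.3511	0.1198
A	N6	14.6026	-5.1273	0.8945
C	C1'	10.1244	-1.1477	0.2623
C	C2'	9.6909	-0.1482	1.2359
C	C3'	8.9291	0.897	0.393
C	C4'	9.671	0.8393	-0.8998
C	O4'	10.2132	-0.499	-1.0314
C	O2'	10.4744	0.0556	2.3904
C	O3'	7.6651	1.506	0.6116
C	C5'	8.3768	0.786	-1.6758
C	O5'	7.73	-0.4837	-1.4681
C	P	7.2122	-1.3568	-2.7049
C	OP1	8.353	-1.5705	-3.6233
C	OP2	6.1289	-0.6034	-3.3749
C	N1	11.1592	-2.1084	0.7059
C	C2	11.2923	-2.4092	2.0462
C	N3	12.2571	-3.305	2.4598
C	C4	13.0889	-3.8999	1.5332
C	C5	12.9558	-3.5991	0.193
C	C6	11.991	-2.7034	-0.2207
C	O2	10.5509	-1.8789	2.872
C	N4	14.0258	-4.7697	1.9349
G	C1'	10.1244	-1.1477	0.2623
G	C2'	9.6909	-0.1482	1.2359
G	C3'	8.9291	0.897	0.393
G	C4'	9.671	0.8393	-0.8998
G	O4'	10.2132	-0.499	-1.0314
G	O2'	10.4744	0.0556	2.3904
G	O3'	7.6651	1.506	0.6116
G	C5'	8.3768	0.786	-1.6758
G	O5'	7.73	-0.4837	-1.4681
G	P	7.2122	-1.3568	-2.7049
G	OP1	8.353	-1.5705	-3.6233
G	OP2	6.1289	-0.6034	-3.3749
G	N9	11.1592	-2.1084	0.7059
G	C8	11.4	-2.4975	2.0079
G	N7	12.4422	-3.4019	1.9968
G	C5	12.8456	-3.5717	0.6881
G	C4	12.0527	-2.7723	-0.1097
G	N3	12.2467	-2.7522	-1.4759
G	C2	13.2336	-3.5315	-2.0442
G	N1	14.0266	-4.3309	-1.2464
G	C6	13.8326	-4.3511	0.1198
G	O6	14.5394	-5.0636	0.8309
G	N2	13.422	-3.512	-3.3708
U	C1'	10.1244	-1.1477	0.2623
U	C2'	9.6909	-0.1482	1.2359
U	C3'	8.9291	0.897	0.393
U	C4'	9.671	0.8393	-0.8998
U	O4'	10.2132	-0.499	-1.0314
U	O2'	10.4744	0.0556	2.3904
U	O3'	7.6651	1.506	0.6116
U	C5'	8.3768	0.786	-1.6758
U	O5'	7.73	-0.4837	-1.4681
U	P	7.2122	-1.3568	-2.7049
U	OP1	8.353	-1.5705	-3.6233
U	OP2	6.1289	-0.6034	-3.3749
U	N1	11.1592	-2.1084	0.7059
U	C2	11.2923	-2.4092	2.0462
U	N3	12.2571	-3.305	2.4598
U	C4	13.0889	-3.8999	1.5332
U	C5	12.9558	-3.5991	0.193
U	C6	11.991	-2.7034	-0.2207
U	O2	10.5509	-1.8789	2.872
U	O4	13.9489	-4.6983	1.9019
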