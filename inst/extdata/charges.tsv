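resname	atom	charge	vdw_radius
A	P	1.17	1.8
A	OP1	-0.78	1.52
A	OP2	-0.78	1.52
A	O5'	-0.5	1.52
A	C5'	0.19	1.7
A	C4'	0.22	1.7
A	O4'	-0.35	1.52
A	C1'	0.24	1.7
A	C3'	0.26	1.7
A	O3'	-0.52	1.52
A	C2'	0.16	1.7
A	O2'	-0.2	1.52
A	N9	-0.013	1.55
A	C8	0.337	1.7
A	N7	-0.563	1.55
A	C5	0.067	1.7
A	C6	0.687	1.7
A	N6	-0.083	1.55
A	N1	-0.723	1.55
A	C2	0.457	1.7
A	N3	-0.653	1.55
A	C4	0.377	1.7
G	P	1.17	1.8
G	OP1	-0.78	1.52
G	OP2	-0.78	1.52
G	O5'	-0.5	1.52
G	C5'	0.19	1.7
G	C4'	0.22	1.7
G	O4'	-0.35	1.52
G	C1'	0.24	1.7
G	C3'	0.26	1.7
G	O3'	-0.52	1.52
G	C2'	0.16	1.7
G	O2'	-0.2	1.52
G	N9	0.015	1.55
G	C8	0.3545	1.7
G	N7	-0.5355	1.55
G	C5	0.2045	1.7
G	C6	0.7445	1.7
G	O6	-0.5255	1.52
G	N1	-0.4455	1.55
G	C2	0.7845	1.7
G	N2	-0.2955	1.55
G	N3	-0.6255	1.55
G	C4	0.2145	1.7
C	P	1.17	1.8
C	OP1	-0.78	1.52
C	OP2	-0.78	1.52
C	O5'	-0.5	1.52
C	C5'	0.19	1.7
C	C4'	0.22	1.7
C	O4'	-0.35	1.52
C	C1'	0.24	1.7
C	C3'	0.26	1.7
C	O3'	-0.52	1.52
C	C2'	0.16	1.7
C	O2'	-0.2	1.52
C	N1	-0.0375	1.55
C	C2	0.7625	1.7
C	O2	-0.6175	1.52
C	N3	-0.7575	1.55
C	C4	0.8325	1.7
C	N4	-0.2075	1.55
C	C5	-0.3875	1.7
C	C6	0.3025	1.7
U	P	1.17	1.8
U	OP1	-0.78	1.52
U	OP2	-0.78	1.52
U	O5'	-0.5	1.52
U	C5'	0.19	1.7
U	C4'	0.22	1.7
U	O4'	-0.35	1.52
U	C1'	0.24	1.7
U	C3'	0.26	1.7
U	O3'	-0.52	1.52
U	C2'	0.16	1.7
U	O2'	-0.2	1.52
U	N1	-0.0266	1.55
U	C2	0.8638	1.7
U	O2	-0.5762	1.52
U	N3	-0.4062	1.55
U	C4	0.8338	1.7
U	O4	-0.6162	1.52
U	C5	-0.3362	1.7
U	C6	0.1538	1.7
MG	MG	2	0.92
HOH	O	0	1.52
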