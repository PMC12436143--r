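aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	0	30	27	30	36	25	27	16	24	22	22	28	19	24	16	22	16	32	26	17
R	30	0	19	21	40	12	14	29	10	33	32	9	27	30	43	26	20	24	20	32
N	27	19	0	14	33	12	11	20	16	37	37	20	32	36	20	15	17	35	30	35
D	30	21	14	0	35	15	12	22	18	40	40	21	35	39	23	18	21	38	33	37
C	36	40	33	35	0	34	37	32	37	37	37	42	36	38	34	25	30	41	38	36
Q	25	12	12	15	34	0	9	22	8	32	32	13	27	30	18	18	14	28	22	30
E	27	14	11	12	37	9	0	23	11	36	35	14	30	34	43	20	18	32	27	33
G	16	29	20	22	32	22	23	0	23	31	31	28	27	33	12	13	15	37	30	27
H	24	10	16	18	37	8	11	23	0	30	29	10	24	28	18	21	15	25	20	28
I	22	33	37	40	37	32	36	31	30	0	5	33	11	10	27	32	25	22	20	9
L	22	32	37	40	37	32	35	31	29	5	0	32	10	9	27	32	24	21	19	10
K	28	9	20	21	42	13	14	28	10	33	32	0	27	29	23	26	20	25	21	31
M	19	27	32	35	36	27	30	27	24	11	10	27	0	10	22	28	20	18	14	11
F	24	30	36	39	38	30	34	33	28	10	9	29	10	0	27	33	24	16	15	14
P	16	43	20	23	34	18	43	12	18	27	27	23	22	27	0	16	11	30	24	23
S	22	26	15	18	25	18	20	13	21	32	32	26	28	33	16	0	14	35	29	29
T	16	20	17	21	30	14	18	15	15	25	24	20	20	24	11	14	0	27	20	22
W	32	24	35	38	41	28	32	37	25	22	21	25	18	16	30	35	27	0	11	25
Y	26	20	30	33	38	22	27	30	20	20	19	21	14	15	24	29	20	11	0	21
V	17	32	35	37	36	30	33	27	28	9	10	31	11	14	23	29	22	25	21	0
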