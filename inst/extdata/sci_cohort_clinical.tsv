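ID	Group	Age	Gender	AIS	NLI	TSI	SCIPI	CPG	NocP	NRS	MAS	SCAT	distance_FS_FH_m	distance_FD_FH_m
01	SCI	53	M	A	C2	32.4	2	N	Y	6	2.67	1.00	n.a.	0.40
02	SCI	31	M	A	T8	13.3	0	N	N	0	2.33	1.17	n.a.	0.40
03	SCI	36	M	A	T4	14.4	1	N	N	0	4.17	1.33	n.a.	0.40
04	SCI	45	F	A	T4	2.7	7	Y	N	5	0.17	0.00	n.a.	0.40
05	SCI	62	M	A	T4	6.1	5	Y	N	7	0.33	0.00	n.a.	0.40
06	SCI	42	F	A	T7	1.2	7	Y	N	7	0.67	0.67	n.a.	0.40
07	SCI	18	F	D	T5	1.1	1	N	Y	1	3.67	0.83	n.a.	0.40
08	SCI	59	M	D	C6	1.5	2	N	Y	1	2.17	0.83	n.a.	0.40
09	SCI	26	F	C	T3	1.7	4	Y	N	7	4.33	1.17	n.a.	0.40
10	SCI	62	F	D	C3	3.8	6	Y	N	7	2.16	0.50	0.42	0.40
11	SCI	63	M	D	T5	8.3	3	N	Y	3	MD	1.67	n.a.	0.40
12	SCI	61	F	D	T5	1.9	3	Y	N	4	0.00	0.00	n.a.	0.40
13	SCI	41	F	D	C5	0.9	5	N	Y	6	MD	0.50	n.a.	0.40
14	SCI	46	M	D	C2	2.0	4	Y	N	8	0.83	0.17	n.a.	0.40
15	SCI	54	M	D	T1	6.7	5	Y	N	6	0.33	0.16	n.a.	0.40
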