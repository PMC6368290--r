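jct	posA	posB	mh	insertion	repeatA	repeatB	geneA	geneB	estimated
1	2581232	27452000	N.i.	N.i.	AluSg	AluSz6	TTC34	SLC9A1	TRUE
2	2684269	14176001	N.i.	N.i.	-	THE1B	TTC34	-	TRUE
3	3290905	64810516	G	-	-	L3	PRDM16	-	FALSE
4	3296814	236176103	CT	-	(CACCC)n	-	PRDM16	NID1	FALSE
5	7682335	12897986	-	-	MIRb	AluYa5	CAMTA1	-	FALSE
6	7685352	236183504	CCTCTT	-	-	AluSx	CAMTA1	NID1	FALSE
7	10775956	21736058	-	GGTTTAAAC	(CACCC)n	AluY	CASZ1	-	FALSE
8	10775956	14443177	-	-	(CACCC)n	THE1B-int	CASZ1	-	FALSE
9	11950223	27642518	C	-	LTR5B	AluSz6	-	-	FALSE
10	11950229	237674299	C	-	LTR5B	-	-	RYR2	FALSE
11	12029894	14870594	GT	-	AluJb	-	PLOD1	-	FALSE
12	13975090	14870595	-	-	L1MC5	-	-	-	FALSE
13	13975102	35045018	-	-	L1MC5	MER41B	-	-	FALSE
14	16136097	23235619	-	-	AluSz6	-	-	EPHB2	FALSE
15	16136098	20149345	-	-	AluSz6	L4	-	-	FALSE
16	16147000	29030516	-	-	AluSx	AT_rich	-	GMEB1	FALSE
17	16147001	23117213	C	-	AluSx	-	-	EPHB2	FALSE
18	20149331	26177921	-	-	L4	L1MB7	-	AUNIP	FALSE
19	21736058	27642518	C	-	AluY	AluSz6	-	-	FALSE
20	23117213	64810516	-	-	-	L3	-	-	FALSE
21	23235618	26177922	-	-	-	L1MB7	EPHB2	AUNIP	FALSE
22	27414473	29030516	GGGC	-	ERVL-E-in	AT_rich	-	GMEB1	FALSE
23	27667160	28083088	-	-	AluY	AluSx1	-	FAM76A	FALSE
24	27667279	246033001	-	-	AluY	-	-	SMYD3	FALSE
25	28083088	35045017	-	-	AluSx1	MER41B	FAM76A	-	FALSE
26	237674294	246030822	-	-	-	L2a	RYR2	SMYD3	FALSE
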