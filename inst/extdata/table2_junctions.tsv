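case	jct	sv_type	chrA	posA	chrB	posB	mh	insertion	repeatA	repeatB
1	1	Translocation	15	55083061	2	209425831	-	-	L1M5	MLT1E1
1	2	Inversion	2	211567929	2	211580840	-	G	L2	-
1	3	Translocation	15	55083064	2	211580844	T	-	L1M5	-
1	4	Translocation	2	212551796	8	129040005	-	-	L1MD1	L2b
1	5	Translocation	2	214880375	8	114508085	-	-	MER72	ERVL-B4-int
2	1	Translocation	1	196997343	5	124956736	-	-	L1MA9	-
2	2	Translocation	1	196997344	10	20816166	-	-	AluJr	L1PA4
2	3	Translocation	10	20816168	5	124956731	TA	-	L1PA4	-
2	4	Deletion	10	4689760	10	19120882	TCA	-	-	-
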