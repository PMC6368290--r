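id	chrA	posA	sideA	chrB	posB	sideB
c1_j1	2	209425831	pter	15	55083064	qter
c1_j2	8	114508085	pter	2	214880375	qter
c1_j3	15	55083061	pter	2	211580844	pter
c1_j4	2	211567929	qter	2	211580785	qter
c1_j5	2	212551796	pter	8	129040005	qter
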