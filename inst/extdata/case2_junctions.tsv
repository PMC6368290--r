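id	chrA	posA	sideA	chrB	posB	sideB
c2_j1	1	196997343	pter	5	124956736	qter
c2_j2	10	20816166	qter	1	196997343	qter
c2_j3	5	124956731	pter	10	20816168	pter
c2_j4	10	4689760	pter	10	19120882	qter
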