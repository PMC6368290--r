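case	chrom	start	end	size_mb	n_genes	disease_genes
1	2	209425211	211567929	2.1	8	-
1	2	212551755	214880375	2.3	3	-
1	8	114508086	129040004	14.5	49	TRPS1;EXT1
2	10	4689760	19120882	14.4	75	GATA3
3	1	3290001	3297000	0.007	1	-
3	1	7682001	7685000	0.003	1	CAMTA1
3	1	12030001	12898000	0.87	11	-
3	1	14176001	14443000	0.27	0	-
3	1	27415001	27452000	0.04	1	-
3	1	236176001	236183000	0.007	1	-
3	1	246031001	246033000	0.002	1	-
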