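ref_seg	pos	refbase	cov	prebase	mismatch	A	G	T	C	N	a	g	t	c	n	single_jump_direct	single_jump_delayed	double_jump	arrest
tdbR00000370|Saccharomyces_cerevisiae|4932|Arg|TCT	57	A	699	C	0.29471	493	8	2	94	0	0	5	5	92	0	0.00000	0.02710	0.00285	0.10941
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT	59	A	961	C	0.37045	605	7	6	125	0	0	7	69	142	0	0.00000	0.00407	0.02238	0.15544
tdbR00000021|Saccharomyces_cerevisiae|4932|Cys|GCA	57	A	405	T	0.21728	317	13	39	0	0	0	7	28	1	0	0.00000	0.00000	0.00000	0.43399
tdbM00000003|Saccharomyces_cerevisiae|4932|Gln|TTG	57	A	475	A	0.15789	400	11	18	1	0	0	12	29	4	0	0.00000	0.00000	0.00000	0.26810
tdbR00000170|Saccharomyces_cerevisiae|4932|Ile|AAT	59	A	919	T	0.38085	569	55	88	6	0	0	67	127	7	0	0.00429	0.00000	0.01072	0.15350
tdbM00000006|Saccharomyces_cerevisiae|4932|Ile|TAT	58	A	373	T	0.25469	278	13	28	4	0	0	7	34	9	0	0.00000	0.00000	0.00000	0.31934
tdbR00000192|Saccharomyces_cerevisiae|4932|Lys|CTT	58	A	2715	G	0.16317	2272	102	103	9	0	0	108	112	9	0	0.00037	0.00000	0.00293	0.07658
tdbR00000193|Saccharomyces_cerevisiae|4932|Lys|TTT	58	A	619	G	0.43942	347	49	75	10	0	0	62	68	8	0	0.00478	0.00000	0.00955	0.16511
tdbR00000323|Saccharomyces_cerevisiae|4932|Pro|TGG	57	A	459	T	0.43573	259	3	69	0	0	0	12	112	4	0	0.00000	0.00000	0.00000	0.18905
tdbR00000324|Saccharomyces_cerevisiae|4932|Pro|TGG	57	A	439	T	0.43508	248	4	56	1	0	0	9	121	0	0	0.00000	0.00000	0.00000	0.20364
tdbR00000443|Saccharomyces_cerevisiae|4932|Thr|AGT	58	A	396	A	0.28283	284	23	23	3	0	0	28	30	5	0	0.00000	0.00222	0.12195	0.38608
tdbR00000444|Saccharomyces_cerevisiae|4932|Thr|AGT	58	A	616	A	0.31656	421	39	47	5	0	0	41	54	9	0	0.00145	0.00000	0.10320	0.30152
tdbR00000464|Saccharomyces_cerevisiae|4932|Val|AAC	59	A	1066	T	0.18386	870	33	55	22	0	0	18	61	7	0	0.00187	0.00000	0.00094	0.69026
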