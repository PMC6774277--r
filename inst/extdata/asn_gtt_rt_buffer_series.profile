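ref_seg	pos	refbase	cov	prebase	mismatch	A	G	T	C	N	a	g	t	c	n	single_jump_direct	single_jump_delayed	double_jump	arrest
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT Reference	58	A	3238	A	0.02471	3158	4	4	33	2	0	5	7	25	0	0.01927	0.00056	0.00000	0.4574
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 0.5 mM Mn	58	A	1380	A	0.04855	1313	4	1	47	3	0	2	0	10	0	0.02404	0.00000	0.00060	0.32355
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 1.0 mM Mn	58	A	3546	A	0.04061	3402	15	9	79	0	0	13	6	22	0	0.02913	0.00000	0.00067	0.14965
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 3.0 mM Mn	58	A	2239	A	0.04332	2142	9	6	37	7	0	12	5	21	0	0.05623	0.00172	0.00138	0.0565
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT Reference	59	A	6311	C	0.90160	621	79	36	3431	6	0	119	25	1994	0	0.00000	0.01048	0.04161	0.84647
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 0.5 mM Mn	59	A	2210	C	0.93167	151	37	59	1238	8	0	37	15	665	0	0.00041	0.01630	0.09902	0.86879
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 1.0 mM Mn	59	A	4454	C	0.95757	189	65	95	2208	1	0	75	35	1786	0	0.00038	0.02481	0.14907	0.70422
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 3.0 mM Mn	59	A	2568	C	0.96145	99	9	9	1149	14	0	7	5	1276	0	0.00000	0.05323	0.16101	0.06965
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT Reference	60	C	42890	C	0.00445	87	30	22	42699	21	20	10	1	0	0	0.00000	0.00000	0.00000	0.36943
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 0.5 mM Mn	60	C	18703	C	0.00733	51	12	10	18566	50	11	3	0	0	0	0.00000	0.00005	0.00000	0.43528
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 1.0 mM Mn	60	C	17706	C	0.00345	17	7	10	17645	10	9	6	2	0	0	0.00006	0.00011	0.00011	0.35852
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT 3.0 mM Mn	60	C	3287	C	0.01156	2	1	9	3249	14	5	5	2	0	0	0.00000	0.00000	0.00030	0.03294
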