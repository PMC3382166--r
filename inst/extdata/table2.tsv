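phospho_peptide	accession	gene_symbol	name	change_in	BCR/ABL_ratio	BCR/ABL_conf	BCR/ABL_called	TEL/PDGFRB_ratio	TEL/PDGFRB_conf	TEL/PDGFRB_called	NPM/ALK_ratio	NPM/ALK_conf	NPM/ALK_called	KITD816V_ratio	KITD816V_conf	KITD816V_called	FLT3ITD_ratio	FLT3ITD_conf	FLT3ITD_called	FIP1L/PDGFRA_ratio	FIP1L/PDGFRA_conf	FIP1L/PDGFRA_called
MDRT[Pho]PPPPT[Pho]LSPAAVTVGR	ENSMUSP00000114916	Phc3	Polyhomeotic-like 3	5	1.56	0.98	TRUE	1.5	0.96	TRUE	1.23	0.79	FALSE	1.69	0.98	TRUE	1.45	0.95	TRUE	1.49	0.96	TRUE
LDSSQLPLQTGLDVPAT[Pho]PR	ENSMUSP00000027768	Ahctf1	Protein ELYS (Protein MEL-28)	5	1.5	0.96	TRUE	1.2	0.74	FALSE	1.44	0.95	TRUE	1.6	0.98	TRUE	1.47	0.96	TRUE	1.57	0.98	TRUE
DSQDTS[Pho]AEQSDHDDEVASLASASGGFGSK	ENSMUSP00000039134	Edc4	Enhancer of mRNA-decapping protein 4	4	0.42	0.99	TRUE	0.95	0.28	FALSE	0.58	0.98	TRUE	1.04	0.18	FALSE	0.38	0.99	TRUE	0.55	0.99	TRUE
GPIHS[Pho]PVELQR	ENSMUSP00000065363	Nfil3	Nuclear factor interleukin-3-regulated protein	4	1.98	0.96	TRUE	1.27	0.75	FALSE	1.75	0.94	TRUE	1.34	0.75	FALSE	2.03	0.96	TRUE	1.84	0.96	TRUE
QSEQPVKPVGPVMDDAAPEDSASPVS[Pho]QQR	ENSMUSP00000106275	Trp53bp1	Tumor suppressor p53-binding protein 1	4	1.9	0.99	TRUE	1.47	0.96	TRUE	1.66	0.98	TRUE	1.41	0.94	FALSE	1.48	0.96	TRUE	1.31	0.87	FALSE
LQPLTSVDS[Pho]DNDFVTPK	ENSMUSP00000107910	Ncapd2	Condensin complex subunit 1	4	2.02	0.99	TRUE	1.9	0.99	TRUE	1.54	0.98	TRUE	2.07	0.99	TRUE	1.17	0.69	FALSE	0.93	0.36	FALSE
ELLLDIGDVS[Pho]ER	ENSMUSP00000026448	A2ACJ2	Fanconi anemia-associated protein	4	0.49	0.99	TRUE	0.45	0.99	TRUE	0.76	0.88	FALSE	0.53	0.99	TRUE	0.6	0.98	TRUE	0.75	0.89	FALSE
S[Pho]PLDNMSR	ENSMUSP00000079818	Etv6	Ets variant gene 6 (TEL oncogene)	4	1.34	0.89	FALSE	1.52	0.97	TRUE	1.77	0.99	TRUE	1.8	0.99	TRUE	1.56	0.98	TRUE	1.34	0.89	FALSE
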