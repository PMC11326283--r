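# Residue library: one entry per line, tab-separated.
# code	fragment	natural	reactive	stereo	bridge
# fragment: side-chain SMILES branch as written from the alpha carbon ("-" = H, glycine).
# reactive: comma-separated tags from {thiol, sidechain_amine, sidechain_carboxyl}, "-" = none.
#   thiol fragments end in S, sidechain_amine in N, sidechain_carboxyl in C(=O)O
#   so cyclization bonds can be realized on the terminal atom.
# stereo: 1 if the alpha carbon is a stereocenter.
# bridge: side-chain SMILES bridging the backbone N to the alpha carbon
#   (proline-like residues), "-" otherwise; bridged entries use "-" fragment.
Ala	C	1	-	1	-
Arg	CCCNC(=N)N	1	-	1	-
Asn	CC(=O)N	1	-	1	-
Asp	CC(=O)O	1	sidechain_carboxyl	1	-
Cys	CS	1	thiol	1	-
Gln	CCC(=O)N	1	-	1	-
Glu	CCC(=O)O	1	sidechain_carboxyl	1	-
Gly	-	1	-	0	-
His	Cc1c[nH]cn1	1	-	1	-
Ile	C(C)CC	1	-	1	-
Leu	CC(C)C	1	-	1	-
Lys	CCCCN	1	sidechain_amine	1	-
Met	CCSC	1	-	1	-
Phe	Cc1ccccc1	1	-	1	-
Pro	-	1	-	1	CCC
Ser	CO	1	-	1	-
Thr	C(C)O	1	-	1	-
Trp	Cc1c[nH]c2ccccc12	1	-	1	-
Tyr	Cc1ccc(O)cc1	1	-	1	-
Val	C(C)C	1	-	1	-
Orn	CCCN	0	sidechain_amine	1	-
Dab	CCN	0	sidechain_amine	1	-
Dap	CN	0	sidechain_amine	1	-
Nle	CCCC	0	-	1	-
Nva	CCC	0	-	1	-
Abu	CC	0	-	1	-
Hse	CCO	0	-	1	-
Hcy	CCS	0	thiol	1	-
Cha	CC1CCCCC1	0	-	1	-
Phg	c1ccccc1	0	-	1	-
Nal	Cc1ccc2ccccc2c1	0	-	1	-
Cit	CCCNC(=O)N	0	-	1	-
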