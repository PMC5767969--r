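cluster_id	aa1	aa2	domains	smiles
albonoursin	F	L	AlbA	C1(C(NC(C(N1)=O)=Cc2ccccc2)=O)=CC(C)C
pulcherrimin_precursor	L	L	CDO_NOX	C1(C(CC(C)C)[N+](C(C(CC(C)C)[N+]1[O-])=O)[O-])=O
mycocyclosin	Y	Y	CYP121	C2(C1Cc4cc(-c3c(ccc(CC(C(N1)=O)N2)c3)O)c(cc4)O)=O
cyclo_WW	W	W		C5(C(Cc2c1c(cccc1)[nH]c2)NC(C(Cc4c3c(cccc3)[nH]c4)N5)=O)=O
cyclo_GG	G	G		C1(CNC(CN1)=O)=O
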