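site	residues	label
P2	IVLAGFWT	L
P2	ISLAGFWT	L
P2	IVDAGFWT	L
P2	IVLAGFWT	L
P2	HVLAGFWT	L
P2	YFWLAPGS	F
P2	YFDLAPGS	F
P2	YFWLAPGS	F
P2	YFYLAPGS	F
P2	YFWLAPGS	F
P2	FWYDRKED	W
P2	TWYHRKED	W
P2	FWYHRKED	W
P2	FWFHRKED	W
P2	FWYHRKED	W
P2	FYWSFNQG	Y
P2	NYWSTNQG	Y
P2	NYWSTNQG	Y
P2	FYWLVNQG	Y
P2	FYWSTNQS	Y
P2	DASVVLIC	A
P2	GASTVLIC	A
P2	GAHTVLIC	A
P2	GASTVLIC	A
P2	GASTVLIC	A
P2	DEQNRKPT	E
P2	DNQNRKCN	E
P2	DEQNHKHT	E
P2	DEQNRKHR	E
P2	DEANRKHT	E
P2	SCTKCHVM	C
P2	SCTAGPVM	C
P2	SCTAGPVM	C
P2	SCTATPVM	C
P2	SCTAGRVM	C
P2	TSNQAGCW	S
P2	TDVEDGCW	S
P2	TSNQNGCW	S
P2	TSNQAGCW	S
P2	TLNQAGCW	S
P2	GPAVLHTY	P
P2	GPAYLSTY	P
P2	FPAVLSTY	P
P2	GPAVLSTY	P
P2	GPAVLSTY	P
P2	RKHEKQNT	K
P2	RKHEDQNT	K
P2	RKHEDQNT	K
P2	RKHEDQNT	K
P2	RKHEPQMT	K
P2	IVEANGSC	V
P2	IILKMGSC	V
P2	IVLAMGSC	V
P2	IVLAMASF	V
P2	IVLSMGSC	V
P2	AGSPVCLQ	G
P2	AGSPVMTQ	G
P2	AGSEVCTQ	G
P2	AGSPVCTQ	G
P2	AGKPVCTQ	G
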