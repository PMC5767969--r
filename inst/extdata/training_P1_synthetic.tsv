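site	residues	label
P1	LIVAFGWS	L
P1	LIMAFGSS	L
P1	LIVAFGWS	L
P1	LIVAFGWS	L
P1	LIVAFGWS	L
P1	FYWLPAGC	F
P1	FPWLPAGT	F
P1	FYWDPAGT	F
P1	FDWLPAGT	F
P1	FYWLPAGT	F
P1	WFYHKGDE	W
P1	WFYHKRDS	W
P1	WFYHKRDE	W
P1	WFYHKRNE	W
P1	WFYHKRDE	W
P1	YFWSTNQH	Y
P1	YFWSTNQH	Y
P1	AWWRTNQH	Y
P1	YFWSTNQH	Y
P1	YFWSTMQH	Y
P1	AGETVLIC	A
P1	AGSTVLIC	A
P1	AESTVLLC	A
P1	WGSTNLIY	A
P1	AGSTVLIE	A
P1	ILQNKRHS	E
P1	EDQNKRHS	E
P1	EDQNKRHS	E
P1	EPQNKRHS	E
P1	EDQNKRHS	E
P1	CPTAGPVM	C
P1	CSTAGPVM	C
P1	CSTAGPVM	C
P1	CSTAGPVV	C
P1	CSTYNPVM	C
P1	STNQAECY	S
P1	STGQAGCP	S
P1	STNQAGCA	S
P1	STNQAGCY	S
P1	FTNQAGYY	S
P1	PGAVLSTF	P
P1	PGAVLWTF	P
P1	PGACLSTF	P
P1	PGAVLSTF	P
P1	PGAVLMTF	P
P1	KRHSDQNS	K
P1	KRHEDQNN	K
P1	KDMEDQNS	K
P1	KRHEDRNS	K
P1	KRHEDQNS	K
P1	VILAMGST	V
P1	GIRAMGST	V
P1	VILAMGNT	V
P1	VILAMGST	V
P1	VILAMGST	V
P1	GATPVCTN	G
P1	GASPVCTN	G
P1	GASPVCTN	G
P1	GASNVCGK	G
P1	GASPVCTN	G
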