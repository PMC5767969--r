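name	category	reaction_ref
CYP121	cdps_tailoring	CYP121
CDO_NOX	cdps_tailoring	CDO_NOX
AlbA	cdps_tailoring	AlbA
Ndas_1145	cdps_tailoring	Ndas_1145
Ndas_1149	cdps_tailoring	Ndas_1149
Amir_4628	cdps_tailoring	Amir_4628
NAT	generic_tailoring	NA
SULT	generic_tailoring	NA
GT1	generic_tailoring	NA
MFS	resistance	NA
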