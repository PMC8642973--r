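gene_a	gene_b
TMPRSS2	ERG
CCDC6	RET
FGFR3	TACC3
LMNA	NTRK1
KIF5B	RET
NCOA4	RET
PAX8	PPARG
SLC34A2	ROS1
SLC45A3	BRAF
TPM3	NTRK1
EML4	ALK
ETV6	NTRK3
EGFR	SEPT14
FGFR3	BAIAP2L1
EWSR1	FLI1
KIAA1549	BRAF
BCR	ABL1
NPM1	ALK
ZFTA	RELA
PAX3	FOXO1
FGFR1	TACC1
RUNX1	RUNX1T1
CBFB	MYH11
PML	RARA
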