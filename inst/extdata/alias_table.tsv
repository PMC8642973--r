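approved_symbol	alias	cytoband
RBPMS	RBPMS	8p12
MET	MET	7q31.2
BCAN	BCAN	1q23.1
NTRK1	NTRK1	1q23.1
KIAA1549	KIAA1549	7q34
BRAF	BRAF	7q34
EML4	EML4	2p21
ALK	ALK	2p23.2
EWSR1	EWSR1	22q12.2
FLI1	FLI1	11q24.3
BCR	BCR	22q11.23
ABL1	ABL1	9q34.12
ETV6	ETV6	12p13.2
NTRK3	NTRK3	15q25.3
NPM1	NPM1	5q35.1
ZFTA	ZFTA	11q13.1
RELA	RELA	11q13.1
PAX3	PAX3	2q36.1
FOXO1	FOXO1	13q14.11
FGFR1	FGFR1	8p11.23
TACC1	TACC1	8p11.23
FGFR3	FGFR3	4p16.3
TACC3	TACC3	4p16.3
TRIM22	TRIM22	11p15.4
KMT2A	KMT2A	11q23.3
TMPRSS2	TMPRSS2	21q22.3
ERG	ERG	21q22.2
CCDC6	CCDC6	10q21.2
RET	RET	10q11.21
LMNA	LMNA	1q22
KIF5B	KIF5B	10p11.22
NCOA4	NCOA4	10q11.23
PAX8	PAX8	2q14.1
PPARG	PPARG	3p25.2
SLC34A2	SLC34A2	4p15.2
ROS1	ROS1	6q22.1
SLC45A3	SLC45A3	1q32.1
TPM3	TPM3	1q21.3
EGFR	EGFR	7p11.2
SEPT14	SEPT14	7p11.2
BAIAP2L1	BAIAP2L1	7q21.3
CLTC	CLTC	17q23.1
FLT3	FLT3	13q12.2
RUNX1	RUNX1	21q22.12
RUNX1T1	RUNX1T1	8q21.3
CBFB	CBFB	16q22.1
MYH11	MYH11	16p13.11
PML	PML	15q24.1
RARA	RARA	17q21.2
SYNA1	SYNA1	1p11
SYNB1	SYNB1	1p11
SYNC1	SYNC1	1p11
SYND1	SYND1	1q11
SYNE1	SYNE1	1q21
SYNF1	SYNF1	1q22
SYNA2	SYNA2	2p11
SYNB2	SYNB2	2p11
SYNC2	SYNC2	2p11
SYND2	SYND2	2q11
SYNE2	SYNE2	2q21
SYNF2	SYNF2	2q22
SYNA3	SYNA3	3p11
SYNB3	SYNB3	3p11
SYNC3	SYNC3	3p11
SYND3	SYND3	3q11
SYNE3	SYNE3	3q21
SYNF3	SYNF3	3q22
SYNA4	SYNA4	4p11
SYNB4	SYNB4	4p11
SYNC4	SYNC4	4p11
SYND4	SYND4	4q11
SYNE4	SYNE4	4q21
SYNF4	SYNF4	4q22
SYNA5	SYNA5	5p11
SYNB5	SYNB5	5p11
SYNC5	SYNC5	5p11
SYND5	SYND5	5q11
SYNE5	SYNE5	5q21
SYNF5	SYNF5	5q22
SYNA6	SYNA6	6p11
SYNB6	SYNB6	6p11
SYNC6	SYNC6	6p11
SYND6	SYND6	6q11
SYNE6	SYNE6	6q21
SYNF6	SYNF6	6q22
SYNA7	SYNA7	7p11
SYNB7	SYNB7	7p11
SYNC7	SYNC7	7p11
SYND7	SYND7	7q11
SYNE7	SYNE7	7q21
SYNF7	SYNF7	7q22
SYNA8	SYNA8	8p11
SYNB8	SYNB8	8p11
SYNC8	SYNC8	8p11
SYND8	SYND8	8q11
SYNE8	SYNE8	8q21
SYNF8	SYNF8	8q22
SYNA9	SYNA9	9p11
SYNB9	SYNB9	9p11
SYNC9	SYNC9	9p11
SYND9	SYND9	9q11
SYNE9	SYNE9	9q21
SYNF9	SYNF9	9q22
SYNA10	SYNA10	10p11
SYNB10	SYNB10	10p11
SYNC10	SYNC10	10p11
SYND10	SYND10	10q11
SYNE10	SYNE10	10q21
SYNF10	SYNF10	10q22
SYNA11	SYNA11	11p11
SYNB11	SYNB11	11p11
SYNC11	SYNC11	11p11
SYND11	SYND11	11q11
SYNE11	SYNE11	11q21
SYNF11	SYNF11	11q22
SYNA12	SYNA12	12p11
SYNB12	SYNB12	12p11
SYNC12	SYNC12	12p11
SYND12	SYND12	12q11
SYNE12	SYNE12	12q21
SYNF12	SYNF12	12q22
SYNA13	SYNA13	13p11
SYNB13	SYNB13	13p11
SYNC13	SYNC13	13p11
SYND13	SYND13	13q11
SYNE13	SYNE13	13q21
SYNF13	SYNF13	13q22
SYNA14	SYNA14	14p11
SYNB14	SYNB14	14p11
SYNC14	SYNC14	14p11
SYND14	SYND14	14q11
SYNE14	SYNE14	14q21
SYNF14	SYNF14	14q22
SYNA15	SYNA15	15p11
SYNB15	SYNB15	15p11
SYNC15	SYNC15	15p11
SYND15	SYND15	15q11
SYNE15	SYNE15	15q21
SYNF15	SYNF15	15q22
SYNA16	SYNA16	16p11
SYNB16	SYNB16	16p11
SYNC16	SYNC16	16p11
SYND16	SYND16	16q11
SYNE16	SYNE16	16q21
SYNF16	SYNF16	16q22
SYNA17	SYNA17	17p11
SYNB17	SYNB17	17p11
SYNC17	SYNC17	17p11
SYND17	SYND17	17q11
SYNE17	SYNE17	17q21
SYNF17	SYNF17	17q22
SYNA18	SYNA18	18p11
SYNB18	SYNB18	18p11
SYNC18	SYNC18	18p11
SYND18	SYND18	18q11
SYNE18	SYNE18	18q21
SYNF18	SYNF18	18q22
SYNA19	SYNA19	19p11
SYNB19	SYNB19	19p11
SYNC19	SYNC19	19p11
SYND19	SYND19	19q11
SYNE19	SYNE19	19q21
SYNF19	SYNF19	19q22
SYNA20	SYNA20	20p11
SYNB20	SYNB20	20p11
SYNC20	SYNC20	20p11
SYND20	SYND20	20q11
SYNE20	SYNE20	20q21
SYNF20	SYNF20	20q22
SYNA21	SYNA21	21p11
SYNB21	SYNB21	21p11
SYNC21	SYNC21	21p11
SYND21	SYND21	21q11
SYNE21	SYNE21	21q21
SYNF21	SYNF21	21q22
SYNA22	SYNA22	22p11
SYNB22	SYNB22	22p11
SYNC22	SYNC22	22p11
SYND22	SYND22	22q11
SYNE22	SYNE22	22q21
SYNF22	SYNF22	22q22
ZFTA	C11orf95	11q13.1
KMT2A	MLL	11q23.3
NTRK1	TRKA	1q23.1
ABL1	ABL	9q34.12
ZFTA	LOC65998	11q13.1
SYND2	AMBIG1	2q11
SYNE9	AMBIG1	9q21
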