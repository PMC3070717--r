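probe_id	gene_id	symbol	chromosome
ACTC1	70	ACTC1	15
BMP4	652	BMP4	14
CDC20	991	CDC20	1
CRYGD	1421	CRYGD	2
DBH	1621	DBH	9
GJB1	2705	GJB1	X
HCCS	3052	HCCS	X
KRT83	3889	KRT83	12
LHCGR	3973	LHCGR	2
MFAP4	4239	MFAP4	17
MPZ	4359	MPZ	1
NHLH1	4807	NHLH1	1
SPARCL1	8404	SPARCL1	4
TACR3	6870	TACR3	4
TAGLN	6876	TAGLN	11
TM9SF1	10548	TM9SF1	14
TPM2	7169	TPM2	9
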