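pathway	gene	role
RTK	BRAF	oncogene
RTK	EGFR	oncogene
RTK	ERBB2	oncogene
RTK	ERBB3	oncogene
RTK	ERBB4	oncogene
RTK	FGFR1	oncogene
RTK	FGFR2	oncogene
RTK	FGFR3	oncogene
RTK	FGFR4	oncogene
RTK	HRAS	oncogene
RTK	KIT	oncogene
RTK	KRAS	oncogene
RTK	MET	oncogene
RTK	NRAS	oncogene
RTK	NF1	tumor_suppressor
HIPPO	NF2	tumor_suppressor
HIPPO	SAV1	tumor_suppressor
HIPPO	WWC1	tumor_suppressor
chromatin_modification	CREBBP	tumor_suppressor
chromatin_modification	EHMT1	tumor_suppressor
chromatin_modification	EHMT2	tumor_suppressor
chromatin_modification	EP300	tumor_suppressor
chromatin_modification	EZH1	tumor_suppressor
chromatin_modification	EZH2	tumor_suppressor
chromatin_modification	KAT2A	tumor_suppressor
chromatin_modification	KAT2B	tumor_suppressor
chromatin_modification	KDM1A	tumor_suppressor
chromatin_modification	KDM1B	tumor_suppressor
chromatin_modification	KDM4A	tumor_suppressor
chromatin_modification	KDM4B	tumor_suppressor
chromatin_modification	KDM5A	tumor_suppressor
chromatin_modification	KDM5B	tumor_suppressor
chromatin_modification	KDM5C	tumor_suppressor
chromatin_modification	KDM6A	tumor_suppressor
chromatin_modification	KDM6B	tumor_suppressor
chromatin_modification	KMT2A	tumor_suppressor
chromatin_modification	KMT2B	tumor_suppressor
chromatin_modification	KMT2C	tumor_suppressor
chromatin_modification	KMT2D	tumor_suppressor
chromatin_modification	KMT2E	tumor_suppressor
chromatin_modification	NSD1	tumor_suppressor
chromatin_modification	SETD2	tumor_suppressor
chromatin_modification	SMYD4	tumor_suppressor
chromatin_modification	SRCAP	tumor_suppressor
SWI_SNF	ACTB	tumor_suppressor
SWI_SNF	ACTL6A	tumor_suppressor
SWI_SNF	ACTL6B	tumor_suppressor
SWI_SNF	ARID1A	tumor_suppressor
SWI_SNF	ARID1B	tumor_suppressor
SWI_SNF	ARID2	tumor_suppressor
SWI_SNF	BCL11A	tumor_suppressor
SWI_SNF	BCL11B	tumor_suppressor
SWI_SNF	BCL6	tumor_suppressor
SWI_SNF	BCL6B	tumor_suppressor
SWI_SNF	BRD7	tumor_suppressor
SWI_SNF	BRD9	tumor_suppressor
SWI_SNF	DPF1	tumor_suppressor
SWI_SNF	DPF2	tumor_suppressor
SWI_SNF	DPF3	tumor_suppressor
SWI_SNF	PBRM1	tumor_suppressor
SWI_SNF	PHF10	tumor_suppressor
SWI_SNF	SMARCA2	tumor_suppressor
SWI_SNF	SMARCA4	tumor_suppressor
SWI_SNF	SMARCB1	tumor_suppressor
SWI_SNF	SMARCC1	tumor_suppressor
SWI_SNF	SMARCC2	tumor_suppressor
SWI_SNF	SMARCD1	tumor_suppressor
SWI_SNF	SMARCD2	tumor_suppressor
SWI_SNF	SMARCD3	tumor_suppressor
SWI_SNF	SMARCE1	tumor_suppressor
PI3K_AKT_mTOR	AKT1	oncogene
PI3K_AKT_mTOR	AKT2	oncogene
PI3K_AKT_mTOR	AKT3	oncogene
PI3K_AKT_mTOR	MTOR	oncogene
PI3K_AKT_mTOR	PIK3CA	oncogene
PI3K_AKT_mTOR	RHEB	oncogene
PI3K_AKT_mTOR	IDH1	oncogene
PI3K_AKT_mTOR	IDH2	oncogene
PI3K_AKT_mTOR	PIK3R1	tumor_suppressor
PI3K_AKT_mTOR	PTEN	tumor_suppressor
PI3K_AKT_mTOR	STK11	tumor_suppressor
PI3K_AKT_mTOR	TSC1	tumor_suppressor
PI3K_AKT_mTOR	TSC2	tumor_suppressor
PI3K_AKT_mTOR	VHL	tumor_suppressor
MYC_family	MYC	oncogene
MYC_family	MYCN	oncogene
MYC_family	MYB	oncogene
TERT	TERT	oncogene
Wnt_beta_catenin	CTNNB1	oncogene
Wnt_beta_catenin	FGF19	oncogene
Wnt_beta_catenin	APC	tumor_suppressor
Wnt_beta_catenin	AXIN1	tumor_suppressor
Wnt_beta_catenin	NCOR1	tumor_suppressor
p53_Rb	CCND1	oncogene
p53_Rb	CCNE1	oncogene
p53_Rb	CDK4	oncogene
p53_Rb	E2F2	oncogene
p53_Rb	E2F3	oncogene
p53_Rb	MDM2	oncogene
p53_Rb	ATM	tumor_suppressor
p53_Rb	CDKN1A	tumor_suppressor
p53_Rb	CDKN2A	tumor_suppressor
p53_Rb	FBXW7	tumor_suppressor
p53_Rb	RB1	tumor_suppressor
p53_Rb	TP53	tumor_suppressor
NRF2	NFE2L2	oncogene
NRF2	KEAP1	tumor_suppressor
NRF2	CUL3	tumor_suppressor
NRF2	SIRT1	tumor_suppressor
NRF2	FH	tumor_suppressor
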