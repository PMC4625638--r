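cohort	algorithm	datatype	cindex	tier
OV	CPSO	EXPR	66	b
OV	CPSO	MIRNA	61	b
OV	CPSO	CNA	64	c
OV	CPSO	MUT	10	c
OV	CPSO	MERGE	65	c
OV	NFS	EXPR	60	a
OV	NFS	MIRNA	53	none
OV	NFS	CNA	56	b
OV	NFS	MUT	11	c
OV	NFS	MERGE	63	c
OV	LASSO	EXPR	68	c
OV	LASSO	MIRNA	62	c
OV	LASSO	CNA	64	c
OV	LASSO	MUT	NA	none
OV	LASSO	MERGE	68	c
LUAD	CPSO	EXPR	74	b
LUAD	CPSO	MIRNA	70	none
LUAD	CPSO	CNA	74	b
LUAD	CPSO	MUT	52	c
LUAD	CPSO	MERGE	75	b
LUAD	NFS	EXPR	71	b
LUAD	NFS	MIRNA	73	b
LUAD	NFS	CNA	65	a
LUAD	NFS	MUT	29	b
LUAD	NFS	MERGE	64	none
LUAD	LASSO	EXPR	72	c
LUAD	LASSO	MIRNA	75	c
LUAD	LASSO	CNA	66	c
LUAD	LASSO	MUT	52	c
LUAD	LASSO	MERGE	78	c
BRCA	CPSO	EXPR	85	c
BRCA	CPSO	MIRNA	82	c
BRCA	CPSO	CNA	92	none
BRCA	CPSO	MUT	38	c
BRCA	CPSO	MERGE	83	c
BRCA	NFS	EXPR	79	none
BRCA	NFS	MIRNA	76	none
BRCA	NFS	CNA	70	none
BRCA	NFS	MUT	28	c
BRCA	NFS	MERGE	84	none
BRCA	LASSO	EXPR	81	c
BRCA	LASSO	MIRNA	80	b
BRCA	LASSO	CNA	83	c
BRCA	LASSO	MUT	53	c
BRCA	LASSO	MERGE	86	c
GBM	CPSO	EXPR	63	c
GBM	CPSO	MIRNA	59	c
GBM	CPSO	CNA	57	b
GBM	CPSO	MUT	16	c
GBM	CPSO	MERGE	59	none
GBM	NFS	EXPR	60	c
GBM	NFS	MIRNA	61	c
GBM	NFS	CNA	58	b
GBM	NFS	MUT	3	b
GBM	NFS	MERGE	63	c
GBM	LASSO	EXPR	60	c
GBM	LASSO	MIRNA	61	c
GBM	LASSO	CNA	53	c
GBM	LASSO	MUT	5	none
GBM	LASSO	MERGE	61	c
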