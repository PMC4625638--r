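algorithm	cohort	size	EXPR	MIRNA	CNA	MUT
CPSO	BRCA	10	6	0	3	1
CPSO	LUAD	9	6	0	3	0
CPSO	GBM	10	2	2	1	5
CPSO	OV	10	6	0	4	0
NFS	BRCA	4	0	0	4	0
NFS	LUAD	4	3	0	1	0
NFS	GBM	9	4	0	5	0
NFS	OV	9	4	0	4	1
LASSO	BRCA	11	4	0	2	5
LASSO	LUAD	9	3	3	1	2
LASSO	GBM	13	10	1	1	1
LASSO	OV	10	10	0	0	0
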