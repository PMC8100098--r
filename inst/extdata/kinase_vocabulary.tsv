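gene_symbol	entrez_id
AURKA	6790
AURKB	9212
AXL	558
CAMK2G	818
CLK1	1195
CSF1R	1436
CSNK1G3	1456
CSNK2A1	1457
CSNK2A2	1459
DYRK1A	1859
FGFR1	2260
FLT1	2321
FLT3	2322
FYN	2534
GSK3B	2932
HIPK4	147746
IRAK4	51135
LCK	3932
MAPK1	5594
MET	4233
NTRK3	4916
PDGFRA	5156
PIM1	5292
PIM2	11040
RET	5979
RPS6KA3	6197
SLK	9748
SRPK1	6732
STK17A	9263
SYK	6850
ABL1	25
EGFR	1956
SRC	6714
BRAF	673
CDK2	1017
MAPK3	5595
JAK2	3717
KIT	3815
MTOR	2475
PLK1	5347
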