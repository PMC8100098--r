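kinase_name,gene_symbol,entrez_id,activity_25ug,activity_250ug,dose_dependent,note
Aurora-B(h),AURKB,9212,56,2,TRUE,
CaMKIIgamma(h),CAMK2G,818,64,86,FALSE,
CK1gamma3(h),CSNK1G3,1456,58,23,TRUE,
CK2alpha1(h),CSNK2A1,1457,65,47,TRUE,
CK2alpha2(h),CSNK2A2,1459,64,43,TRUE,
CLK1(h),CLK1,1195,4,NA,FALSE,high-dose value typographically ambiguous in the source; stored as missing
Fms(h),CSF1R,1436,59,58,FALSE,
FGFR1(h),FGFR1,2260,69,43,TRUE,
Fyn(h),FYN,2534,63,63,FALSE,
GSK3beta(h),GSK3B,2932,56,39,TRUE,
Met(h),MET,4233,43,8,TRUE,
Pim-1(h),PIM1,5292,69,18,TRUE,
Ret(h),RET,5979,61,70,FALSE,
Syk(h),SYK,6850,63,2,TRUE,
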