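kinase_name,protein,gene_symbol,entrez_id,concentration,activity_pct
Aurora-A(h),Aurora-A,AURKA,6790,25,76
Aurora-B(h),Aurora-B,AURKB,9212,25,56
Axl(h),AXL,AXL,558,25,73
CaMKIIgamma(h),CaMK2gamma,CAMK2G,818,25,64
CLK1(h),CLK1,CLK1,1195,25,4
Fms(h),Fms,CSF1R,1436,25,59
CK1gamma3(h),CK1gamma3,CSNK1G3,1456,25,58
CK2alpha1(h),CK2alpha1,CSNK2A1,1457,25,65
CK2alpha2(h),CK2alpha2,CSNK2A2,1459,25,64
DYRK1A(h),DYRK1A,DYRK1A,1859,25,80
FGFR1(h),FGFR,FGFR1,2260,25,69
Flt1(h),Flt-1,FLT1,2321,25,78
Flt3(h),FLT3,FLT3,2322,25,74
Fyn(h),Fyn,FYN,2534,25,63
GSK3beta(h),GSK3beta,GSK3B,2932,25,56
HIPK4(h),HIPK4,HIPK4,147746,25,71
IRAK4(h),IRAK4,IRAK4,51135,25,80
Lck(h),Lck,LCK,3932,25,79
MAPK1(h),MAPK1(ERK2),MAPK1,5594,25,78
Met(h),Met,MET,4233,25,43
TrkC(h),TRKC,NTRK3,4916,25,72
PDGFRalpha(h),PDGFRalpha,PDGFRA,5156,25,76
Pim-1(h),Pim1,PIM1,5292,25,69
Pim-2(h),Pim2,PIM2,11040,25,71
Ret(h),Ret,RET,5979,25,61
Rsk2(h),RSK2,RPS6KA3,6197,25,78
SLK(h),SLK,SLK,9748,25,75
SRPK1(h),SRPK1,SRPK1,6732,25,74
DRAK1(h),DRAK1,STK17A,9263,25,79
Syk(h),Syk,SYK,6850,25,63
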