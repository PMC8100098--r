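id,component_name,pubchem_cid
CDDP01,Danshensu,11600642
CDDP02,Tanshinone I,114917
CDDP03,Cryptotanshinone,160254
CDDP04,Tanshinone IIA,164676
CDDP05,Dihydrotanshinone I,11425923
CDDP06,Salvianolic acid A,5281793
CDDP07,Salvianolic acid B,11629084
CDDP08,Salvianolic acid B1,24518070
CDDP09,Salvianolic acid D,75412558
CDDP10,Salvianolic acid G,11683160
CDDP11,Protocatechuic aldehyde,8768
CDDP12,Rosmarinic acid,5281792
CDDP13,Lithospermic acid,6441498
CDDP14,Ginsenoside-Rg1,441923
CDDP15,Ginsenoside-Rb1,9898279
CDDP16,Ginsenoside-Rh1,12855920
CDDP17,Ginsenoside-Rd,11679800
CDDP18,Notoginsenoside R1,441934
CDDP19,Ginsenoside Re,441921
CDDP20,Borneol,1201518
CDDP21,Isoborneol,6973640
CDDP22,Caffeic acid,689043
CDDP23,Tanshinone IIB,9926694
CDDP24,Methylenetanshinquinone,105118
CDDP25,Salvianolic acid C,13991590
CDDP26,Ginsenoside-Rf,441922
CDDP27,Ginsenoside-F2,9918692
CDDP28,Ginsenoside-F1,9809542
CDDP29,Ginsenoside-Rb2,6917976
CDDP30,Ginsenoside-Rb3,12912363
CDDP31,Ginsenoside-Rg2,21599924
CDDP32,Notoginsenoside-R2,21599925
CDDP33,20(S)-Ginsenoside Rg3,9918693
CDDP34,20(R)-Ginsenoside Rg3,46887680
CDDP35,Miltirone,160142
CDDP36,Protocatechuic acid,72
CDDP37,Catechol,289
CDDP38,Vanillic acid,8468
CDDP39,4-Hydroxy-3-methyloxyphenyl lactic acid,160637
CDDP40,Quercetin,5280343
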