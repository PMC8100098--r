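drug_id,target_id,ic50_mean,ic50_sd,units
CDDP,AURKB,0.0053,0.0011,mg/mL
CDDP,MET,0.0039,0.0001,mg/mL
CDDP,PIM1,0.0358,0.0138,mg/mL
CDDP,SYK,0.0019,0.0007,mg/mL
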