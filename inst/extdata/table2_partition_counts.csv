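target_source,all_targets,kinase_targets,kinomex_screened
known,262,55,37
predicted,377,121,92
common,160,28,20
total,479,148,109
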