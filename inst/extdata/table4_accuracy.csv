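target_source,kinomex_screened,in_full_kp_panel,active_targets,accuracy_pct
known,37,37,15,40.5
predicted,92,89,26,29.2
common,20,20,11,55
total,109,106,30,28.3
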