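matrix,n_pairs,n_metabolites_panel,n_metabolites_measured
plasma,39,188,153
rbc,40,188,143
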