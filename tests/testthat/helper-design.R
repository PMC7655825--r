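# One full-size design shared across test files (seeded, deterministic).
shared_design <- design_barcode_sets(96, seed = 1)
shared_union <- c(shared_design$s_set$sequences, shared_design$q_set$sequences)
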