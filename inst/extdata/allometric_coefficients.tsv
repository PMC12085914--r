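taxon_group	coefficient_a	exponent_b	source
Dinoflagellata	0.216	0.939	protist regression
Bacillariophyta	0.288	0.811	diatom regression
Ciliophora	0.216	0.939	protist regression
Haptophyta	0.216	0.939	protist regression
Dictyochophyceae	0.216	0.939	protist regression
other	0.216	0.939	protist regression
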