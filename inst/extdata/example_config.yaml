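# Example report configuration. Paths are resolved relative to the
# working directory; `counts` may be replaced by a per-animal `genotypes`
# CSV (header animal_id,locus,genotype), optionally joined to a
# `phenotypes` CSV (header animal_id,parity,litter_size) for the
# association stage.
counts: smad_genotype_counts.csv
alpha: 0.05
digits: 2
out_dir: report
seed: 1
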