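# eight-generation scenario with 21,000 recorded animals, five traits,
# 301 contemporary groups per generation and partial genotyping
# (10/30/40/50% in the last four generations); see sim_preset("dataset1").
# n_snp can be lowered for structural studies that do not need all markers.
preset: dataset1
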