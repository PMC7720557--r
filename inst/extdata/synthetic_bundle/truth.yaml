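root_age: 280.0
d: 0.001
r: 0.983
s: 0.5
n_extant: 1
n_fossil: 31
n_sa: 0
base_rate: 0.02
clock_variance: 0.02
clock_model: igr
autapomorphy_fraction: 0.1908397
seed: 7
n_taxa: 32
n_characters: 131
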