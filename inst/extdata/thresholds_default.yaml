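logp_hydrophobic_min: 1.0
logp_polar_max: -1.0
charge_positive_min: 0.5
charge_negative_max: -0.5
pi_positive_min: 8.0
pi_negative_max: 6.0
mw_small_max: 120.0
mw_large_min: 180.0
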