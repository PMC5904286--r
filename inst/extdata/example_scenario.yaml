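# Simulator scenario: a two-fold dilution series with NTC chips,
# Bl-04-like per-well false-positive rate, no viability effects.
true_copies_per_ul_template: 20000
dead_fraction: 0
pma_efficacy: 0.9
lysis_efficiency: 1
false_positive_rate_per_well: 0.0114
false_negative_rate_per_well: 0
qualified_wells_range: [15000, 18200]
dilution_factors: [1, 2, 4, 8, 16, 32, 64]
replicates: 3
n_ntc: 3
target_id: SIM-BL04
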