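# Survey prevalence exists only at the collapsed level for two
# cardiovascular pairs; their separately-counted rows are summed.
chf_heart_disease:
  - congestive_heart_failure
  - heart_disease
heart_attack_stroke:
  - heart_attack
  - stroke
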