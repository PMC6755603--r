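# Cohort-mode run: generate a calibrated synthetic cohort and cost it at
# patient level. Patient-level costing uses configurable unit rates and does
# not reproduce the published component table exactly (see the methods
# vignette); component-table mode is the canonical reproduction path.
seed: 20160501
locale: default
productivity_rule: all_days
cohort:
  n: 132
scenarios:
  - prevalence: 0.008
  - prevalence: 0.009
market_shares: [0.04, 0.12]
sensitivity: default
reference_rate: 0.381
output_dir: "."
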