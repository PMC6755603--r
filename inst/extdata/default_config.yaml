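# Default run: reproduce the published per-case table and its
# extrapolations (component-table mode).
seed: 20160501
locale: default
productivity_rule: all_days
component_table:
  path: null          # null = packaged reference table (n = 132)
scenarios:
  - prevalence: 0.008
    label: "prevalence 0.8% (656,000 patients)"
  - prevalence: 0.009
    label: "prevalence 0.9% (738,000 patients)"
market_shares: [0.04, 0.12]
sensitivity: default
reference_rate: 0.381
output_dir: "."
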