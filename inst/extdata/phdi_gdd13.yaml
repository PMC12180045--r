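variant_name: gdd13
energy_basis_target: 2500.0
components:
- name: whole_grains
  kind: adequacy
  unit: grams_per_day
  optimal_low: 232.0
  optimal_high: 232.0
- name: whole_fruits
  kind: adequacy
  unit: grams_per_day
  optimal_low: 200.0
  optimal_high: 200.0
- name: nonstarchy_vegetables
  kind: adequacy
  unit: grams_per_day
  optimal_low: 300.0
  optimal_high: 300.0
- name: nuts_seeds
  kind: adequacy
  unit: grams_per_day
  optimal_low: 50.0
  optimal_high: 50.0
- name: legumes
  kind: adequacy
  unit: grams_per_day
  optimal_low: 100.0
  optimal_high: 100.0
- name: unsaturated_oils
  kind: adequacy
  unit: grams_per_day
  optimal_low: 40.0
  optimal_high: 40.0
- name: fish_shellfish
  kind: bidirectional
  unit: grams_per_day
  optimal_low: 28.0
  optimal_high: 28.0
  max_ref: 100.0
- name: starchy_vegetables
  kind: bidirectional
  unit: grams_per_day
  optimal_low: 50.0
  optimal_high: 50.0
  max_ref: 200.0
- name: dairy
  kind: bidirectional
  unit: grams_per_day
  optimal_low: 250.0
  optimal_high: 250.0
  max_ref: 1000.0
- name: red_processed_meat
  kind: bidirectional
  unit: grams_per_day
  optimal_low: 14.0
  optimal_high: 14.0
  max_ref: 28.0
- name: eggs
  kind: bidirectional
  unit: grams_per_day
  optimal_low: 13.0
  optimal_high: 13.0
  max_ref: 26.0
- name: saturated_fats
  kind: moderation
  unit: percent_energy
  optimal_low: 0.0
  optimal_high: 0.0
  max_ref: 3.8
- name: added_sugars
  kind: moderation
  unit: percent_energy
  optimal_low: 0.0
  optimal_high: 0.0
  max_ref: 5.0
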