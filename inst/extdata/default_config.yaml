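# Default pipeline configuration (mirrors default_pipeline_config()).
# Any field omitted falls back to the package default; unknown fields are
# rejected with their path.
seed: 1
generator:
  n_patients: 10000
  n_centers: 30
  n_donors: 1500
model:
  backend: cox          # cox | rsf | km (curve stack)
  horizon: 25           # years
  steps_per_year: 12    # monthly curve grid
  num_trees: 300
  importance_backend_pair: [rsf, cox]
  importance_train: 4000
  importance_eval: 1000
  importance_num_trees: 150
  importance_repeats: 10
assumptions:
  n_grid: [0.5, 1, 1.5, 2, 3, 4, 5]   # assumed xenograft survival, years
  q: 75                                # highest-priority percentile
scenarios:
  set: [base, inactive_accrual, living_donor_priority, highest_priority]
  priority_multiplier: 5
  cohort_ids: [1, 2, 3, 4]
relist:
  level: individual     # individual | cohort
metrics:
  taus: [1, 2, 3]       # analysis periods, years
  min_correct: 15       # suppression threshold
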