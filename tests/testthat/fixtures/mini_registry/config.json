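{
  "n_patients": 3,
  "n_centers": 2,
  "n_donors": 2,
  "seed": 1,
  "horizon_years": 25
}
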