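{
  "settings": [1],
  "n_iterations": 25,
  "master_seed": 20260909,
  "models": ["a", "b", "c", "d"],
  "size_grid": [
    {"total_patients": 2000, "n_studies": 8, "mean_size": 250},
    {"total_patients": 1000, "n_studies": 10, "mean_size": 100}
  ],
  "heterogeneity_grid": [
    {"i2_intercept": 0, "i2_exposure": 0},
    {"i2_intercept": 0.5, "i2_exposure": 0.5}
  ]
}
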