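{
  "seed": 20,
  "n_respondents": 283,
  "n_items": 18,
  "n_factors": 3,
  "outlier_fraction": 0.05,
  "outlier_magnitude": 4,
  "retest_reliability": 0.873,
  "validity": 0.65,
  "readability_counts": {"words": 968, "sentences": 121, "syllables": 1356},
  "n_subjects": 200,
  "weights": [6, 1.5, 3.5],
  "threshold": 0.5,
  "efa_args": {"rotation": "varimax"},
  "adaboost_rounds": 5
}
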