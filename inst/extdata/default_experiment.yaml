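# Default experiment: published cohort structure and hyperparameters.
cohort:
  n_mild: 220
  n_severe: 188
  n_features: 40
  missing_rate: 0
fl:
  k: 3
  rounds: 350
  epochs: 5
  batch_size: 10
  eta: 0.001
  split: [7, 3]
  hidden: [32, 16]
  activation: relu
  weighted: false
missing_threshold: 0.10
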