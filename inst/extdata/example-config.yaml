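# Example study configuration for run_study(read_run_config(...))
seed: 1
trial:
  n_patients: 2000
models: [induction, maintenance_only, maintenance_from_induction]
hyperparams: tuned
k_folds: 10
tuning:
  n_iter: 25
  k_folds: 5
bootstrap:
  B: 500
  strategy: with_replacement
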