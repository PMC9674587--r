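# Demo analysis: small simulated cohort, full pipeline.
simulate:
  n_modes: 3
  n_subjects: 4
  noise_sd: 0.05
  subject_jitter_sd: 0.1
extraction:
  restarts: 10
  k_max: 5
crossval:
  n_remove: 1
  reps: 10
seed: 42
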