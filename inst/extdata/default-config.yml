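seed: 1
synth:
  n_trials: 200.0
  srate: 200.0
  duration: 1.8
  sigma_base: 0.75
  impulse_window:
  - 1.3
  - 1.5
  reduction_fraction: 0.3
  n_channels: 17.0
s3:
  n_seeds: 100.0
  early_baseline:
  - 0.0
  - 0.1
  late_baseline:
  - 0.4
  - 0.6
  pre_window:
  - 1.0
  - 1.28
  impulse_window:
  - 1.3
  - 1.5
  n_folds: 8.0
power:
  n_sessions: 12.0
  n_trials: 64.0
  n_orientations: 8.0
  tuning_gain_high: 2.5
  tuning_gain_low: 0.0
  srate: 100.0
  duration: 0.8
  decode_times:
  - 0.15
  - 0.2
  - 0.25
  - 0.3
  - 0.35
  - 0.4
  - 0.45
  - 0.5
  - 0.55
  - 0.6
  - 0.65
  - 0.7
  window:
  - 0.2
  - 0.4
  split_window:
  - 0.2
  - 0.4
  n_resamples: 200.0
  n_splitfolds: 2000.0
  n_shuffles: 200.0
  n_shuffle_folds: 200.0
models:
  n_exc: 512.0
  n_inh: 128.0
  n_trials: 100.0
  n_trials_control: 40.0
  drive_silent: 1.5
  drive_bump: 8.0
  drive_boost: 5.0
  fano_baseline:
  - 0.7
  - 2.5
  drive_window:
  - 2.5
  - 3.0
  boost_window:
  - 3.0
  - 3.5
  n_boot: 2000.0
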