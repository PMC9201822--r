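# Shipped study profile: full-size session structure and the default
# preprocessing/feature/classification parameters.
out_dir: oddballerp_run
master_seed: 1
log_level: INFO
session:
  n_blocks: 8
  trials_per_block: 30
  trial_duration: 6
  deviant_fraction: 0.3333333333333333
  sampling_rate: 250
  inter_trial_gap: [1.3, 2.0]
  stimulus_delay: 1.0
cohort:
  n_subjects: 8
  modalities: [visual_only, audio_visual]
  amp_scale_sd: 0.2
  latency_shift_sd: 6
  latency_jitter_sd: 6
  noise_level: 12
  blink_rate: 10
noise:
  pink_exponent: 1
  alpha_freq: 10
  alpha_rms: 4
  line_freqs: [50, 100]
  line_amps: [5, 2]
  drift_rms: 20
  blink_amplitude: 80
  trial_amp_sd: 0.1
filters:
  notch_freqs: [50, 100]
  notch_halfwidth: 2
  bp_low: 0.5
  bp_high: 40
  bp_order: 1000
  notch_order: 500
epochs:
  window: [-0.5, 1.0]
exclude_channels: [O1, PO7]
ocular:
  method: regression
  threshold: 0.8
rejection:
  z_var: 3
  z_kurt: 3
averaging:
  n_select: 38
  select: random
features:
  profile: paper-dims
cv:
  k: 10
  train_fraction: 0.8
  scheme: repeated_split
  stratified: true
svm:
  cost: 1.0
conditions: [explosion, burning]
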