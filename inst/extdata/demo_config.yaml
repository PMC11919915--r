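# Desk-scale demonstration configuration: a reduced synthetic cohort that
# runs the full simulate -> preprocess -> cluster -> aggregate -> backfit ->
# parameters -> statistics chain in a few minutes on one CPU while keeping
# enough subjects for the planted brain-behavior correlations to reach
# Bonferroni-corrected significance.
seed: 2026
cohort:
  n_subjects: 16
  n_channels: 32
  fs: 250
  n_classes: 7
  sessions_per_stage: [2, 2, 2]
  session_duration_s: 20
  dwell_mean_ms: 80
  snr: 4
preprocess:
  enabled: true
  bandpass: false        # synthetic signal is already band-limited and
                         # drift-free; see the methods vignette
  detect_bads: true
  use_neighbors: false   # synthetic noise is spatially white; see vignette
microstates:
  k: 7
  n_init: 20
  min_peak_distance: 10
  aggregate_n_iter: 50
stats:
  alpha: 0.05
  unit: subject_stage
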