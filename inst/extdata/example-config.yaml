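# Example pipeline configuration for erpcluster::read_pipeline_config().
# A desk-scale run; raise groups/n_trials/n_permutations for a full study.
seed: 1
groups:
  MT: 12
  CT: 10
timepoints: [T1, T2, T3]
plan: default
n_trials: 10
n_channels: 32
sfreq: 256
t_start: -0.5
t_end: 0.8
stat:
  alpha: 0.05
  n_permutations: 500
  min_simultaneous_channels: 2
  analysis_window_ms: [0, 600]
contrasts: [time_F, group_main, pairwise, interaction]
stim_classes: [cue, target]
preprocess: true
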