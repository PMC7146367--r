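# 5-limb-position study shape: 8 channels, 8 motions, 10 repetitions,
# 5 positions at 1000 Hz (2 synthetic subjects, 1 s trials).
generator:
  n_subjects: 2
  n_channels: 8
  condition_kind: "position"
  conditions: [1, 2, 3, 4, 5]
  reps_per_condition: 10
  fs: 1000
  trial_duration: 1.0
  seed: 1
preprocess:
  notch: false
features:
  sets: ["TD"]
evaluate:
  classifiers: ["lda"]
  frameworks: ["intra", "inter", "single_vs_all"]
  seed: 1
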