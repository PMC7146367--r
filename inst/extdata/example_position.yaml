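# Small position-confound example: 1 subject, 3 positions, 4 motions,
# 3 repetitions, 0.5 s trials. Runs end-to-end in seconds.
generator:
  n_subjects: 1
  n_channels: 4
  motion_classes: ["no-motion", "power", "pinch", "wrist-flex"]
  condition_kind: "position"
  conditions: [1, 2, 3]
  reps_per_condition: 3
  fs: 1000
  trial_duration: 0.5
  seed: 7
preprocess:
  notch: false          # synthetic data carries no line interference
features:
  sets: ["TD"]
evaluate:
  classifiers: ["lda"]
  frameworks: ["intra", "inter", "single_vs_all"]
  seed: 7
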