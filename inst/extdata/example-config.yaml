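# Example experiment configuration for `eegvit sweep --config`.
# A small synthetic cohort, the desk-scale transformer, and the
# window-length sweep at the default 90% overlap.
cohort:
  n_subjects: 12
  fraction_delirium: 0.5
  duration: 60
  seed: 1
  effect: {delta: 2.0}
preprocess:
  highpass_hz: 0.5
  lowpass_hz: 40
  ica_enabled: false
slice_seconds: [0.1, 0.5, 1.0, 1.6, 5.0]
overlap: [0.9]
domain: [time]
model:
  image_side: 64
  patch_side: 8
  embed_dim: 64
  depth: 2
  heads: 4
  mlp_ratio: 2
  batch_size: 32
  learning_rate: 0.001
  epochs: 5
split_seed: 1
test_fraction: 0.25
max_slices_per_recording: 40
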