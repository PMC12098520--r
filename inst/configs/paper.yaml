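# Full-scale preset mirroring the published protocol (GPU-recommended;
# hours per fold on CPU): 10 subjects, reference architecture,
# 150 training epochs, batch 16, Adam at 2e-5.
cohort:
  n_subjects: 10
  epochs_per_subject: 800
  shift_magnitude: 1.0
model:
  profile: reference     # (128,128,10) -> (8,8,256) -> (32,256)
  lambda: 1.0
  use_se: true
  use_discriminator: true
training:
  epochs: 150
  batch_size: 16
  lr: 2.0e-5
  optimizer: adam
evaluation:
  bootstrap_B: 1000
  bootstrap_level: 0.95
seed: 1
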