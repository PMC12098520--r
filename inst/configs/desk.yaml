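# Desk-scale preset: runs end to end on one CPU in minutes.
cohort:
  n_subjects: 3
  epochs_per_subject: 20
  shift_magnitude: 1.0
model:
  profile: desk          # 32 x 32 pooled input, narrow stages
  lambda: 1.0
  use_se: true
  use_discriminator: true
training:
  epochs: 5
  batch_size: 16
  lr: 1.0e-3            # Adam default scale for the small desk model
  optimizer: adam
evaluation:
  bootstrap_B: 200
  bootstrap_level: 0.95
seed: 1
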