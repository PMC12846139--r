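# Demo pipeline configuration: 8 sampled models, the fast 16-muscle
# bilateral set, one standardized suite at 25 Hz, short training.
seed: 1
n_profiles: 8
muscle_set: reduced16
motion:
  fs: 25
  cycle_period: 8
so: {}
train:
  epochs: 60
  patience: 10
envelope:
  resolution: 48
  alpha: Inf
subject:
  restriction:
    sector: [flexion_pos, lateral_neg]
    factor: 0.6
outdir: neckforce_run
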