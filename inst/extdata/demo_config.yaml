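# Demonstration pipeline: simulate a mouse RR record, spectral analysis,
# a small record-length convergence study and a two-group comparison.
# All stages are deterministic given the seed.
seed: 17
simulate:
  duration: 30
periodogram:
  fmin: 0.05
  fmax: 2.0
  step: 0.025
  normalize: true
band_power: {}
duration_study:
  n_sims: 20
  durations: [2, 8, 32, 64]
compare:
  n_per_group: 15
  effect_size: 0.8
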