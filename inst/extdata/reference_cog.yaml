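# Reference configuration: 5 demand sites, per-site stopping probability
# 0.4 (N_s = 2 * 0.4 * 5), half the population stationary, dimensionless
# decay k_d L / v = 0.6.
targets:
  f_s: 0.5
  N_s: 4.0
  khat_d: 0.6
  M: 1500
  n: 5
  model: cog
sim:
  n_steps: 100000
  n_iter: 100
  seed: 1
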