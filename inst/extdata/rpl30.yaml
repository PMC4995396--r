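# mRNA degradation, reduced state-dependent delay model
# (ACT1-construct parameter estimates)
model:
  id: rpl30
  s0: 100
  y0: 23
  k: 0.1260
  d: 1.7184
simulation:
  t_end: 80
  reps: 200
  seed: 11
  record_n: 17
units: min
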