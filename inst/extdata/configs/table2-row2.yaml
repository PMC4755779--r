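# As table2-row1 but with correlation 0.8.
task: mc-experiment
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5}
options:
  scenario: regime
  sigma: 0.2
  rho: 0.8
  method: monte_carlo
  n_samples: 1000000
seed: 20151020
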