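# Dominant-allele invasion experiment (uncorrelated draws of
# (r_{1/2}, r_1), sd 0.2). The p_{1/2} behind the published numbers is not
# printed; 0.5 is a synthetic choice, so this row is a demonstration only.
task: mc-experiment
model:
  "n": 2
  dominance: dominant
  p: {"1/2": 0.5}
options:
  scenario: invasion
  sigma: 0.2
  rho: 0.0
  method: monte_carlo
  n_samples: 1000000
seed: 20151020
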