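# Invasion outcome probabilities, recessive allele, uncorrelated draws
# (mean 1, sd 0.1) of (r_{1/4}, r_{1/2}) at p_0 = 0.2, p_{1/4} = 0.4.
task: mc-experiment
model:
  "n": 2
  dominance: recessive
  p: {"0": 0.2, "1/4": 0.4}
options:
  scenario: invasion
  sigma: 0.1
  rho: 0.0
  method: analytic
seed: 20151020
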