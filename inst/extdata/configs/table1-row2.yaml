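# As table1-row1 but with correlation 0.8 between the two efficiencies.
task: mc-experiment
model:
  "n": 2
  dominance: recessive
  p: {"0": 0.2, "1/4": 0.4}
options:
  scenario: invasion
  sigma: 0.1
  rho: 0.8
  method: analytic
seed: 20151020
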