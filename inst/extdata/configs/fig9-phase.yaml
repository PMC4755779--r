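# Invasion regions over (r_{1/6}, r_{1/4}) for double and triple mating,
# with the p values of the triple-mating example set.
task: phase
model:
  "n": 3
  dominance: recessive
  p: {"0": 0.1, "1/6": 0.25, "1/4": 0.325, "1/2": 0.7}
  r: {"1/6": 1.0, "1/4": 1.0, "1/2": 1.16, "1": 1.0}
options:
  axes: ["1/6", "1/4"]
  r_z1: {from: 0.95, to: 1.35, by: 0.005}
  r_z2: {from: 0.95, to: 1.35, by: 0.005}
  n_values: [2, 3]
  what: invasion
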