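# Invasion regions over (r_{1/4}, r_{1/2}) for n = 1 and n = 2 at
# p_0 = 0.2, p_{1/4} = 0.4 (recessive allele).
task: phase
model:
  "n": 2
  dominance: recessive
  p: {"0": 0.2, "1/4": 0.4, "1/2": 0.6}
  r: {"1/4": 1.0, "1/2": 1.0, "1": 1.0}
options:
  axes: ["1/4", "1/2"]
  r_z1: {from: 0.95, to: 1.35, by: 0.005}
  r_z2: {from: 0.95, to: 1.35, by: 0.005}
  n_values: [1, 2]
  what: invasion
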