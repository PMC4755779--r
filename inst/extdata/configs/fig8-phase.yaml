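# Invasion regions for a dominant allele over (r_{1/2}, r_1), n = 1 and 2.
# The p_{1/2} used for the published panel is not printed; 0.5 here is a
# synthetic choice for demonstration.
task: phase
model:
  "n": 2
  dominance: dominant
  p: {"1/2": 0.5}
  r: {"1/2": 1.0, "1": 1.0}
options:
  axes: ["1/2", "1"]
  r_z1: {from: 0.8, to: 2.2, by: 0.02}
  r_z2: {from: 0.8, to: 2.2, by: 0.02}
  n_values: [1, 2]
  what: invasion
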