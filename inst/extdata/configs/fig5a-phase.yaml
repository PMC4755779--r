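# Four-regime phase diagram over (r_{1/2}, r_1) at p_0 = 0.5, n = 1.
task: phase
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5, "1/2": 0.75}
  r: {"1/2": 1.0, "1": 1.0}
options:
  axes: ["1/2", "1"]
  r_z1: {from: 0.5, to: 1.5, by: 0.01}
  r_z2: {from: 0.5, to: 1.5, by: 0.01}
  what: regime
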