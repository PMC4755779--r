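# Coexistence: invasion start converging to an interior attractor.
task: simulate
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5, "1/2": 0.75}
  r: {"1/2": 1.0869, "1": 1.1321}
options:
  initial: invasion
  epsilon: 1.0e-2
  horizon: 1.0e6
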