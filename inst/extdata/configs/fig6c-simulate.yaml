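# Bistability: a mixed start at AA0 = 0.27, aa0 = 0.73 (the companion start
# at 0.26/0.74 converges to the other pure state).
task: simulate
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5, "1/2": 0.75}
  r: {"1/2": 1.0669, "1": 1.1521}
options:
  initial: {AA0: 0.27, aa0: 0.73}
  horizon: 1.0e4
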