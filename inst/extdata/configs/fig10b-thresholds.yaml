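# Second triple-mating example set (sublinear p, linear r).
task: threshold
model:
  "n": 3
  dominance: recessive
  p: {"0": 0.2, "1/6": 0.5, "1/4": 0.6}
  r: {"1/6": 1.04, "1/4": 1.06, "1/2": 1.12}
options:
  n_values: [1, 2, 3]
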