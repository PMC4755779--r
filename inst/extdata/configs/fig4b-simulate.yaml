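# Invasion demonstration for n = 2 (p_0 = 0.2, p_{1/4} = 0.4,
# p_{1/2} = 0.6, r_{1/2} = 1.24, r_1 = 1.6). The published caption does not
# print r_{1/4}; 1.15 here is a synthetic choice above the invasion
# threshold 6.6/6.0 = 1.1.
task: simulate
model:
  "n": 2
  dominance: recessive
  p: {"0": 0.2, "1/4": 0.4, "1/2": 0.6}
  r: {"1/4": 1.15, "1/2": 1.24, "1": 1.6}
options:
  initial: invasion
  epsilon: 1.0e-2
  horizon: 1.0e5
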