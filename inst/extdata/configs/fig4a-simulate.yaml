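# Invasion demonstration for n = 1 (p_0 = 0.1, r_1 = 1.29). The published
# caption does not print r_{1/2}; 1.25 here is a synthetic choice above the
# invasion threshold 6.2/5.3 ~ 1.170.
task: simulate
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.1, "1/2": 0.55}
  r: {"1/2": 1.25, "1": 1.29}
options:
  initial: invasion
  epsilon: 1.0e-2
  horizon: 1.0e5
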