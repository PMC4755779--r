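# Single-mating stability worked example: p_0 = 0.6, r_{1/2} = 1.05;
# the sterility allele is stable iff r_1 > 1.105 (here r_1 = 1.15: stable).
task: classify
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.6, "1/2": 0.9}
  r: {"1/2": 1.05, "1": 1.15}
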