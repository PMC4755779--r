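# Double-mating stability worked example: p_{1/2} = 0.9, r_{1/2} = 1.05;
# stable iff r_1 > 1.087 (here r_1 = 1.10: stable). p_{1/4} is needed only
# for the invasion half of the classification and is not part of the worked
# example; 0.75 is a synthetic filler between p_0 and p_{1/2}.
task: classify
model:
  "n": 2
  dominance: recessive
  p: {"0": 0.6, "1/4": 0.75, "1/2": 0.9}
  r: {"1/4": 1.02, "1/2": 1.05, "1": 1.10}
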