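# Triple mating can open the door: with these printed p and r tables the
# sterility allele invades for n = 3 but not n = 1 or 2.
task: threshold
model:
  "n": 3
  dominance: recessive
  p: {"0": 0.1, "1/6": 0.25, "1/4": 0.325}
  r: {"1/6": 1.095, "1/4": 1.117, "1/2": 1.16}
options:
  n_values: [1, 2, 3]
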