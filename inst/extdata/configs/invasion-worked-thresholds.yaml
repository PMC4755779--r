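# Worked invasion thresholds for single and double mating at
# p_0 = 0.8, p_{1/4} = 0.9: r_{1/2} > 1.027 (n = 1), r_{1/4} > 1.012 (n = 2).
task: threshold
model:
  "n": 2
  dominance: recessive
  p: {"0": 0.8, "1/4": 0.9}
options:
  n_values: [1, 2]
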