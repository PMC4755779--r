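# Regime classification at the parameter set of simulation panel B
# (n = 1, recessive; p_{1/2} is arbitrary here: it cancels in Aa1 colonies).
task: classify
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5, "1/2": 0.75}
  r: {"1/2": 1.0669, "1": 1.1321}
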