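# Wild-type re-invasion of the all-sterile state: perturb the all-a state
# with 1e-3 of aa queens that mated once with a wild-type male.
task: simulate
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5, "1/2": 0.75}
  r: {"1/2": 1.0669, "1": 1.1321}
options:
  initial: stability
  epsilon: 1.0e-3
  horizon: 1.0e4
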