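# Invasion-and-fixation simulation: perturb the all-wild-type state with
# 1e-3 of AA queens that mated once with a mutant male. Second-order
# transient: the horizon is long, but the adaptive solver crosses it fast.
task: simulate
model:
  "n": 1
  dominance: recessive
  p: {"0": 0.5, "1/2": 0.75}
  r: {"1/2": 1.0869, "1": 1.1521}
options:
  initial: invasion
  epsilon: 1.0e-3
  horizon: 1.0e6
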