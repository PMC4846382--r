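schema: '1'
model: reduced
label: experiment
network:
  w: 2.0
simulation:
  duration: 350000.0
  dt: 0.5
  discard: 50000.0
  record_every: 2.0
analysis:
  active_threshold: 0.05
  le_unit: 3.0
  min_consistent: 5.0
perturb: ~
seeds: []
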