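schema: '1'
model: large_scale
label: experiment
network:
  'n': 100.0
  p: 0.15
  w: 2.5
  e_l_mean: -62.0
  e_l_sd: 0.93
  g_nap_mean: 5.0
  g_nap_sd: 0.5
simulation:
  duration: 50000.0
  dt: 0.1
  discard: 20000.0
  record_ids: []
  record_every: 10.0
analysis:
  bin_width: 10.0
  on_threshold: 5.0
  min_gap: 50.0
  la_threshold: 50.0
  la_rule: peak
  window: 100.0
  window_threshold: 20.0
seeds:
  population: 1.0
  topology: 2.0
  init: 3.0
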