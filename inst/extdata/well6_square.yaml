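# 6-well hydrogel, four needles in a square, the most ablative protocol:
# 2300 V x 8 pulses delivered over all six electrode pairs.
geometry:
  plate_format: 6
  coculture: false
  grid_spacing_cm: 0.02
  conductivity_S_per_m: 0.027
electrodes:
  layout: square
  spacing_cm: 1.4
plan:
  - pair: all
    amplitude_V: 2300
    n_pulses: 8
sweep:
  E_min_V_per_cm: 200
  E_max_V_per_cm: 2500
  step_V_per_cm: 20
thresholds:
  exp_V_per_cm: 544
  rep_V_per_cm: 800
seed: 1
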