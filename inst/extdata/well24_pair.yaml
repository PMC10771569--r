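# 24-well monoculture hydrogel, two-needle pair, single activation.
# Conductivity calibrated from resistance readouts (constant model).
geometry:
  plate_format: 24
  coculture: false
  grid_spacing_cm: 0.01
  conductivity_S_per_m: 0.027
electrodes:
  layout: pair
  spacing_cm: 0.8
plan:
  - pair: [E1, E2]
    amplitude_V: 1100
    n_pulses: 100
    pulse_width_us: 100
    frequency_Hz: 1
sweep:
  E_min_V_per_cm: 200
  E_max_V_per_cm: 1200
  step_V_per_cm: 1
thresholds:
  exp_V_per_cm: 544
  rep_V_per_cm: 800
simulate:
  true_threshold_V_per_cm: 544
  noise_cv: 0.05
  n_samples: 9
seed: 42
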