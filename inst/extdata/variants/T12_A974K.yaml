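# Synthetic-data parameters: vinculin-T12-A974K (T12 with an extra
# lysine at 974). 16 major charge states; C->SO onset at 120 V like T12
# but with a short-lived SO state that proceeds early to O; FAs
# destabilised under Y27632.
name: T12_A974K
mass: 116757            # Da; free
charge_states:          # 16 major states: 16+ .. 31+
  z:      [15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29,
           30, 31, 32]
  weight: [0.02, 0.120, 0.203, 0.319, 0.466, 0.630, 0.790, 0.919, 0.991,
           0.991, 0.919, 0.790, 0.630, 0.466, 0.319, 0.203, 0.120, 0.02]
peak_width_mz: 6.0
spectrum_noise: 0.03
ciu_charge: 17
state_ccs:
  C:  {centroid: 6164, width: 120}
  SO: {centroid: 6850, width: 120}
  O:  {centroid: 7279, width: 120}
transitions:            # onset 120 V; SO narrow (O already at ~165 V)
  c_so: {mid: 124, scale: 3.0}
  so_o: {mid: 165, scale: 5.0}
drift_noise: 0.003
mean_ions_per_voltage: 2000
ensemble:               # some extended population, smaller than mVin
  extended_fraction: 0.10
  extended_ccs_min: 7400
  extended_ccs_max: 11000
  compact_charges: [19, 24]
  extended_charges: [25, 45]
fa:
  lognormal: {mu: 0.30, sigma: 0.50}
  decay: {rate: 0.04, plateau: 0.45, rate_sd: 0.01}   # destabilising; free
  bleach_rate: 0.005
seed: 7
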