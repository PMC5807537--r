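# Synthetic-data parameters: vinculin-T12 (D974A, K975A, R976A, R978A;
# weakened tail-D4 interface). 11 major charge states; early C->SO
# transition at 120 V; long-lived SO state; FAs large and stabilised
# (no Y27632 decay).
name: T12
mass: 116700            # Da; free (four alanine substitutions)
charge_states:          # 11 major states: 16+ .. 26+
  z:      [14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28]
  weight: [0.02, 0.02, 0.121, 0.258, 0.467, 0.713, 0.919, 1.0, 0.919,
           0.713, 0.467, 0.258, 0.121, 0.02, 0.02]
peak_width_mz: 6.0
spectrum_noise: 0.03
ciu_charge: 17
state_ccs:
  C:  {centroid: 6108, width: 120}
  SO: {centroid: 6847, width: 120}
  O:  {centroid: 7173, width: 120}
transitions:            # C->SO onset 120 V; SO persists to ~215 V
  c_so: {mid: 124, scale: 3.0}
  so_o: {mid: 200, scale: 8.0}
drift_noise: 0.003
mean_ions_per_voltage: 2000
ensemble:
  extended_fraction: 0.0
  extended_ccs_min: 7400
  extended_ccs_max: 13200
  compact_charges: [19, 24]
  extended_charges: [25, 56]
fa:
  lognormal: {mu: 0.25, sigma: 0.50}   # large/long FAs; free
  decay: {rate: 0.0, plateau: 1.0, rate_sd: 0.0}     # completely stabilised
  bleach_rate: 0.005
seed: 7
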