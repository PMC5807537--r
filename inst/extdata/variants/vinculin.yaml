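# Synthetic-data parameters: wild-type human vinculin.
# Fields marked "free" are not published values; they are fixed once so
# that the analysis modules reproduce the published counts, centroids and
# onsets, and are not tuned per run.
name: vinculin
mass: 117000            # Da; free (monomer mass consistent with an
                        # envelope near 5,700 m/z, strongest state 20+)
charge_states:          # 7 major states (>= 5% base peak): 17+ .. 23+
  z:      [15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25]
  weight: [0.003, 0.024, 0.121, 0.391, 0.791, 1.0, 0.791, 0.391, 0.121, 0.024, 0.003]
peak_width_mz: 6.0      # Th; free
spectrum_noise: 0.03    # multiplicative; free
ciu_charge: 17          # charge-reduced state used for CIU
state_ccs:              # experimental CIU state centroids (A^2)
  C:  {centroid: 6266, width: 120}
  SO: {centroid: 6970, width: 120}
  O:  {centroid: 7268, width: 120}
transitions:            # logistic mixing; C->SO onset 140 V, C persists
                        # to 180 V (gradual); O rises above ~195 V
  c_so: {mid: 160, scale: 9.8}
  so_o: {mid: 210, scale: 8.0}
drift_noise: 0.003      # multiplicative drift jitter; free
mean_ions_per_voltage: 2000   # free
ensemble:               # vinculin is essentially all-compact in solution
  extended_fraction: 0.0
  extended_ccs_min: 7400
  extended_ccs_max: 13200
  compact_charges: [19, 24]
  extended_charges: [25, 56]
fa:
  lognormal: {mu: -0.35, sigma: 0.55}  # um^2 log-space; small FAs; free
  decay: {rate: 0.02, plateau: 0.4, rate_sd: 0.005}    # initial slope 1.2 %/min
  bleach_rate: 0.005                   # 1/min; free
seed: 7
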