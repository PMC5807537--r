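# Synthetic-data parameters: metavinculin (68-residue acidic insert
# between hinge and tail). Bimodal solution ensemble: a compact
# vinculin-like population plus ~40% extended conformers reaching
# 13,200 A^2 on high charge states; CIU C->SO transition is abrupt at
# ~140 V.
name: metavinculin
mass: 124300            # Da; free (vinculin + 68-residue insert)
charge_states:          # compact envelope 17+..25+ plus a broad extended
                        # tail of high charge states (into 29+..55+)
  z:      [17, 18, 19, 20, 21, 22, 23, 24, 25,
           26, 28, 30, 32, 34, 36, 38, 40, 42, 44, 46, 48, 50, 52, 54, 55]
  weight: [0.07, 0.25, 0.62, 0.95, 1.0, 0.80, 0.48, 0.22, 0.09,
           0.16, 0.17, 0.18, 0.18, 0.18, 0.17, 0.17, 0.16, 0.16, 0.15,
           0.15, 0.14, 0.13, 0.12, 0.10, 0.08]
peak_width_mz: 6.0
spectrum_noise: 0.03
ciu_charge: 17
state_ccs:
  C:  {centroid: 6281, width: 120}
  SO: {centroid: 7056, width: 120}
  O:  {centroid: 7363, width: 120}
transitions:            # abrupt C->SO at ~140 V; pronounced O state
  c_so: {mid: 140, scale: 2.0}
  so_o: {mid: 195, scale: 8.0}
drift_noise: 0.003
mean_ions_per_voltage: 2000
ensemble:               # ~40% extended, up to 13,200 A^2
  extended_fraction: 0.40
  extended_ccs_min: 7400
  extended_ccs_max: 13200
  compact_charges: [19, 24]
  extended_charges: [25, 56]
fa:
  lognormal: {mu: -0.20, sigma: 0.55}
  decay: {rate: 0.035, plateau: 0.35, rate_sd: 0.008}  # FA-destabilising; free
  bleach_rate: 0.005
seed: 7
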