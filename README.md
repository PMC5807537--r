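# vinlock

Quantitative analysis of the two-step unlocking of vinculin's
autoinhibitory head-to-tail interaction, for structural biologists and
mechanobiologists working with native ion-mobility mass spectrometry
(IM-MS), collision-induced unfolding (CIU) and focal-adhesion (FA)
imaging.

Vinculin's tail bundle (Vt) locks onto its head (Vh = D1-D4) at two
sites: a large, mostly hydrophobic Vt-D1 interface (~2085 Å² buried)
and a small, largely electrostatic Vt-D4 interface (~696 Å²).
Activation releases the lock in two steps,

    C  (closed)  →  SO (semi-open, Vt-D4 released)  →  O (open),

which CIU resolves as three conformer families with distinct collision
cross sections (CCS) and voltage thresholds, and which cell imaging
connects to FA growth and force-dependence. The package implements:

- **structio** — PDB/mmCIF reading, domain partitioning, Shrake–Rupley
  SASA, buried interface areas (half-buried-SASA convention),
  hydrogen-bond censuses and cross-variant bond comparison.
- **anchors** — grid/ray cavity detection and single-residue
  anchoring-spot mapping (rigid side-chain probes scored by
  Lennard-Jones + screened Coulomb + atomic solvation), with partner
  matching; supports anchor *identity* recovery, not literature ΔG.
- **ccs3d** — projection-approximation CCS (seeded orientation
  averaging, unbiased rasterisation) and rigid-body semi-open/open
  model building with tether and clash screening.
- **imms** — charge-state envelope analysis (harmonic-safe charge
  assignment), traveling-wave drift-time → CCS power-law calibration
  (`ccs' = a·t'^b` after EDC correction and charge/reduced-mass
  scaling), compact/extended ensemble profiling.
- **ciu** — CIU fingerprints (voltage × CCS), conformer detection by a
  shared-component Gaussian mixture (common centroids/widths,
  per-voltage occupancies, BIC model choice), transition onset /
  completion / gradual-vs-abrupt classification, variant comparison.
- **famorph** — per-FA area / Feret length / intensity from labelled
  masks, log-normal size fits, exponential-reference bleaching
  correction, plateau-exponential Y27632 decay fits with FA-bootstrap
  CIs.
- **synthgen** — seeded generators for every input (spectra,
  calibrants, CIU records, ensembles, FA image series) with per-variant
  YAML defaults transcribing the published summary values; the
  analysis/generator pairs form parameter-recovery tests.

## Worked example

```r
library(vinlock)

model <- default_calibration()          # TWIMS power law: a = 350, b = 0.55
v     <- variant_params("vinculin")

# native spectrum -> charge states
cs <- detect_charge_states(gen_spectrum(v, seed = 7))
cs
#> charge states: 7 major (of 9 detected), mass 117003 Da, envelope centre 5884 Th

# CIU run -> fingerprint -> conformer states and transitions
fp <- build_fingerprint(gen_ciu(v, seed = 7), model, v$mass)
st <- detect_states(fp, seed = 7)
states_table(st)
#>   label centroid    width v_first v_last
#> 1     C 6266.192 120.1074      50    180
#> 2    SO 6970.538 121.0793     140    225
#> 3     O 7265.670 122.6636     195    240
detect_transitions(st)
#>   from_state to_state onset_voltage completion_voltage coexistence_width    mode
#> 1          C       SO           140                180                40 gradual
#> 2         SO        O           195                225                30 gradual
```

The closed conformer sits at 6,266 Å² and persists to 180 V while the
semi-open state already appears at 140 V — the wide 40 V coexistence is
what "gradual" means operationally, and it is the signature that
distinguishes wild-type vinculin from the abrupt variants
(`compare_variants()` over the four packaged parameter sets puts the
T12 forms' onsets at 120 V and metavinculin's abrupt switch at 140 V).

The FA arm runs the same way from a generated time-lapse:

```r
ds   <- gen_fa_dataset(v, n_fas = 1000, frames = 60, seed = 7)
fi   <- fa_intensity_series(ds$labels, ds$frame_paths, ds$times)
corr <- bleach_correct(fi$series, ds$reference)
corr$intensity <- corr$intensity / corr$intensity[1]
fit_decay(corr, fa_matrix = bleach_correct(fi$fa_matrix, ds$reference))
#> decay fit: rate 0.0208 /min [0.0205, 0.0211], plateau 0.42,
#>            initial slope 1.20 %/min [1.18, 1.22]
```

i.e. FA fluorescence after Rho-kinase inhibition decays with an initial
slope of ~1.2 %/min for wild-type vinculin, while the T12 parameter set
yields a flat, stabilised curve.

A one-call pipeline (`reproduce(out_dir)`) chains every stage and a thin
CLI wrapper is installed at
`system.file("exec", "vinlock", package = "vinlock")`.

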