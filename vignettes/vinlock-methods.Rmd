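---
title: "Methods: quantifying the two-step unlocking of vinculin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the two-step unlocking of vinculin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological question

Vinculin couples integrin-based focal adhesions (FAs) to the actin
cytoskeleton. In its resting state the molecule is autoinhibited: the
five-helix tail bundle (Vt) binds the head (Vh, domains D1-D4) at two
separate sites, a large mostly hydrophobic Vt-D1 interface and a much
smaller, largely electrostatic Vt-D4 interface. Activation requires
releasing this head-to-tail lock. This package implements, end to end,
the quantitative analyses that support a two-step unlocking model:
closed (C) to semi-open (SO, one interface released - assigned to Vt-D4)
to open (O, tail detached), and connects the gas-phase unfolding
behaviour of four vinculin forms (wild type, metavinculin, T12,
T12-A974K) to their effects on focal-adhesion size and force dependence.

Because no raw instrument or microscope data are deposited for this
system, the package pairs every analysis stage with a seeded synthetic
generator whose defaults transcribe the published summary numbers. The
tests are parameter-recovery tests: the generator plants a truth, the
analysis must find it.

## Crystal-interface anatomy (`structio`)

Structures are read from PDB/mmCIF via bio3d; waters are excluded,
zero-occupancy atoms dropped, alternate locations reduced to the
highest-occupancy copy so all geometry is deterministic.

*Domain partition.* The deposited structures do not print residue
ranges, so the partition lives in an editable YAML
(`inst/extdata/partition_vinculin.yaml`): D1 1-252, D2 253-485,
D3 486-717, D4 718-836, hinge 837-895, Vt 896-1066, metavinculin insert
916-983 with a +68 tail-numbering offset. We end D4 at 836 (not 835)
because the opening-model analysis treats residue 836 as the D4-side
marker; with 836 in the head, the marker pair (875 in the hinge, 836 in
D4) measures a real head-tail separation.

*SASA.* Shrake-Rupley with a deterministic Fibonacci point lattice
(default 960 points, probe 1.4 Å). Because a fixed lattice is not
rotation invariant, coordinates are first rotated into a canonical
principal-axes frame (signs fixed by third moments) and snapped to
1e-6 Å; any rigidly moved copy of a structure then produces
bit-identical areas. Coincident atoms share boundary quadrature points
evenly instead of double-counting.

*Interface area.* Half the buried SASA,
(SASA(a) + SASA(b) - SASA(a+b))/2 per chain, averaged over chains (the
PISA convention; the printed 2085/696 Å² values for Vt-D1/Vt-D4 are on
this scale). All three SASA evaluations share the canonical frame of
the complex, so non-contacting domains give exactly zero.

*Hydrogen bonds.* The deposited models carry no hydrogens, so the
criterion is distance-only between heavy atoms that can donate (N/O
with an attachable proton by residue chemistry; proline backbone N
excluded) and accept (N/O with a lone pair): short < 3.5 Å,
long <= 4.0 Å, matching the two tiers drawn in the crystal-structure
figures. Cross-variant comparisons match bonds by donor/acceptor
residue + atom identity after the +68 metavinculin offset.

## Anchoring spots (`anchors`)

An anchoring spot is a small surface cavity plus the single amino-acid
side chain that binds it favourably. Cavity detection is a grid/ray
("LIGSITE"-style) procedure: cells outside every van der Waals sphere
but in probe reach of the surface are solvent; rays marched along the
26 lattice directions (6 Å) count how enclosed each cell is; cells with
>= 70% blocked directions are pocket cells (a convex surface blocks
only ~half), clustered by 26-connectivity. Depth is the largest
distance from a member cell to open solvent.

Probes are rigid idealised side chains (one canonical extended rotamer
per type, atoms from C-beta; C-alpha included for Thr/Ile). Scoring is
a deliberately coarse semi-empirical sum: Lennard-Jones (element-level
parameters), Coulomb with distance-dependent dielectric eps = 4r
reduced by up to half with the fraction of protein burial around the
probe (the approaching protein displaces screening water), and an
atomic-solvation term on the buried area of the contact (apolar burial
favourable, polar/charged burial penalised). Each cavity x probe is
optimised from many seeded random starts by Nelder-Mead over the six
rigid degrees of freedom.

The package does **not** claim to reproduce literature binding free
energies numerically - the energy model, parameters and sampling of the
original tool are not published. The supported claim is recovery of
anchor-residue *identities* (which residues of the partner domain sit
in strong spots, default cutoff -3 kcal/mol) and the qualitative
asymmetry between the two head-tail interfaces (few strong spots at
Vt-D4, many at Vt-D1).

## Theoretical CCS and opening models (`ccs3d`)

The theoretical collision cross section is the projection
approximation: the mean, over uniformly random orientations (seeded
quaternions, default 3000), of the projected shadow area of the atoms
drawn as disks of radius r_vdW + gas radius (default 1.0 Å; the method
behind the published 6,460 Å² value is a vendor tool whose algorithm and
gas are unstated, which the ±5% acceptance band absorbs). The shadow is
rasterised at 1.0 Å with a random sub-cell origin per orientation,
making the counting estimator unbiased (a single atom reproduces the
analytic disk to <0.1%). A global scale factor (default 1.0) is exposed
for users who calibrate against other CCS methods.

Semi-open/open models displace the tail module (hinge + Vt, so the
marker residue 875 travels with the tail) as a rigid body; chain
continuity across the partially disordered hinge is intentionally not
modelled (no loop building). Poses are accepted if the 875-836 C-alpha
separation stays within an extended-linker tether (130 Å ~ 39 residues
x 3.3 Å) and heavy-atom clashes stay under a cap. `scan_opening()`
sweeps separation increases with random tether-respecting poses and
reports mean ± sd CCS per separation; `assign_state_models()` is
deliberately one-to-many, because distinct geometries share CCS values.

## Charge states and TWIMS calibration (`imms`)

Peak detection smooths lightly (5-bin running mean), takes prominent
local maxima separated by >= 20 Th, and centroids on the raw signal.
Charges are assigned by scanning candidate charges for the highest-m/z
peak and scoring the consistency of the implied neutral masses;
because integer multiples of the true charges are exactly as
self-consistent (harmonics), the lowest-charge assignment among the
best is taken. "Major" states default to >= 5% of the base peak.

Traveling-wave calibration is the standard power-law protocol: drift
times corrected for the mass-dependent transport delay
(t' = t - EDC * sqrt(m/z) / 1000, EDC 1.57), literature CCS reduced by
charge and reduced mass in N2 (28.0134 Da), and ln-ln least squares for
ccs' = a t'^b. Calibrant identities are not published for this system;
the generator ships a clearly synthetic calibrant table
(globular-scaling CCS, native-like charges) whose drift times are
solved exactly from the generating coefficients, so a zero-noise fit
recovers them to machine precision, and real-data users supply their
own CSV.

Ensemble profiling converts per-charge records to CCS, isolates the
compact population robustly (two-means split, then median/MAD core so
low-end extended ions cannot inflate the compact sd) and classifies
everything above compact centroid + 3 sd as extended.

## CIU fingerprints and state detection (`ciu`)

Fingerprints are voltage x CCS intensity maps (50-240 V in 5 V steps,
17+ charge state by default), row-normalised with per-row ion counts
retained. Conformer detection fits a **shared-component Gaussian
mixture**: component centroids and widths are common to all voltages,
only the weights vary per voltage. This encodes the paper-level
interpretation that the same three conformers exist throughout the
ramp, and it stabilises the fit where a state holds only a few percent
of the signal. The EM is weighted by ion counts, multi-started from
seeded random quantile spreads, and the component count (up to 3) is
chosen by BIC. Components are labelled C, SO, O in centroid order.

A state is *present* at a voltage when its occupancy is >= 0.10 (the
printed onsets are reproduced by this threshold on the generator
defaults; it is a config value, since no operational definition of
"appears" is published). For each adjacent pair, onset = first voltage
the new state is present, completion = last voltage the old state is
present, coexistence = completion - onset, and a transition is gradual
when coexistence >= 15 V (three grid steps) - wide C/SO coexistence
(140-180 V) is what distinguishes wild-type vinculin from the abrupt
variants.

## Focal-adhesion morphometry and decay (`famorph`)

Segmentation is out of scope (the published quantification used custom
unpublished code on real images); the module consumes labelled masks.
Area is pixel count x pixel area; length is the maximal Feret diameter
over pixel centres (the published analysis does not define "length";
this is the conservative choice and is configurable); classes are
half-open (small < 1 µm², short < 2 µm). Sizes are fitted by log-normal
maximum likelihood with normal-approximation (or bootstrap) 95% CIs.

Photobleaching correction divides by a smoothed reference series. The
default smoother fits a mono-exponential to the reference - bleaching is
first-order photochemistry - because running-window smoothers are biased
at the series ends on a decaying curve, which otherwise imprints a
spurious ~1% early drop on flat (stabilised) FA series. The Y27632
response is fitted as I(t) = plateau + (1-plateau) exp(-rate t) with
bounds (plateau in [0,1], rate >= 0); the plateau term exists because
T12 curves are flat, and a pure exponential is the plateau -> 0 limit.
The initial slope, 100 * rate * (1-plateau) %/min, is the headline
readout; CIs come from a bootstrap over adhesions.

## The synthetic generators (`synthgen`)

One YAML per variant (inst/extdata/variants/) holds the generator
truth; fields transcribing published values (Table-level state
centroids 6266/6970/7268 Å² etc., onsets 120/140/180 V, 7/11/16 major
charge states, ~40% extended up to 13,200 Å², 1.2 %/min initial slope)
are annotated as such, and everything unpublished (peak widths, noise
levels, logistic sharpness, ion counts, masses, bleach rate, FA size
parameters) is marked *free* and was fixed once to realistic
instrument-scale values - e.g. 2,000 ions per voltage step, 6 Th peak
width, 3% intensity noise, 0.3% drift jitter, 0.5%/min bleaching. State
mixing uses two logistic transitions in voltage; CIU drift times are
drawn by inverting the calibration truth so the analysis-side
calibration round-trips exactly. FA images place non-overlapping
ellipses (log-normal areas, aspect ~2.5) on a 1024² grid of 0.1 µm
pixels with per-adhesion decay-rate heterogeneity (the initial slope is
linear in the rate, so the population-mean slope is preserved) and
Gaussian read noise.

What the generators deliberately do **not** emulate: overlapping or
unresolved charge-state peaks, drift-gas pressure drifts, detector
saturation, FA segmentation errors, FA translocation and shape change
over time, and cell-to-cell variability. Passing recovery tests
therefore demonstrates correctness of the estimators under clean,
published-scale conditions - not robustness to every real-instrument
artefact.

## Reproducibility and numerical choices

Every stochastic routine takes an explicit seed (quaternion orientation
draws, EM multi-starts, pose sampling, all generators); rerunning any
generator with the same seed is byte-identical, including the TIFFs.
EM sigma floors at one CCS bin; zero-intensity fingerprint rows are
flagged, never normalised; probe clashes score +Inf but the optimiser
sees a softened linear penalty so it can climb out; fits that cannot
converge (flat decay series) return rate 0 with a flag instead of
erroring.

Problem sizes used by the packaged checks - 2,000 ions per voltage,
10,000 ensemble ions, 1,000 adhesions over 60 one-minute frames,
20-seed recovery loops, 3,000 CCS orientations - were chosen as
desk-scale settings that keep every recovery well inside its tolerance.

The structure-dependent checks (interface areas 2085/696 Å², Table-level
hydrogen-bond distances, theoretical CCS 6,460 Å² and the 8,325 Å²
displaced model, anchor-identity recovery) require the deposited
crystal structure (PDB 1TR2), which is not redistributed with the
package; point `options(vinlock.structure_dir = ...)` at a directory
containing `1tr2.pdb` to run them.

## Known limitations

- The anchoring-spot energy scale is coarse; only residue identities
  and interface asymmetry are supported claims.
- Projection approximation systematically underestimates CCS for very
  concave shapes relative to trajectory methods; the scale factor is
  the coarse remedy.
- Rigid-body opening models ignore hinge conformational entropy and
  chain continuity.
- The CIU mixture assumes Gaussian conformer peaks on the CCS axis and
  at most three states.
- Decay CIs bootstrap adhesions within one field; they do not capture
  between-cell variance.
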