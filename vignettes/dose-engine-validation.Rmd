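---
title: "Validating proton PBS dose engines with synthetic phantoms and gamma analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating proton PBS dose engines with synthetic phantoms and gamma analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

protonqa reproduces, at desk scale, the workflow used to commission a Monte
Carlo proton dose engine against an established analytical pencil-beam (APB)
engine and planar detector measurements: synthetic heterogeneous phantoms
stand in for CT-scanned anatomy, a virtual ionization-chamber array stands in
for the physical detector, and the agreement between "measured" and computed
dose is quantified with 2D/3D global gamma analysis including a search for
the depth of best agreement. This vignette documents the models, their
assumptions, the tunable parameters, and what the synthetic study can and
cannot show about real measurements.

## The shared physics model

Both engines are built on one parameterized proton physics model
(`proton_physics()`), so differences between them reflect their *transport
approximations*, not their cross sections.

* **Range-energy**: the Bragg-Kleeman power law `R = 10 * alpha * E^p` mm
  with `alpha = 0.0022` cm/MeV^p and `p = 1.77`. Its derivative supplies the
  parameterized Bethe-Bloch stopping power `S(E) = E^(1-p) / (10 alpha p)`;
  other materials scale by their relative stopping power (RSP), so the
  solid-water phantom material (RSP 1.03) loses energy 3% faster per mm than
  water. A 150 MeV proton has `S = 0.54` MeV/mm and a range of 156 mm.
* **Energy-loss straggling**: Gaussian per step with the Bohr variance rate,
  0.0087 MeV^2 per mm of water, scaled by RSP as a proxy for relative
  electron density. Integrated over a full 150 MeV track this yields a
  stopping-depth spread of about 1.0-1.1% of range, the textbook value for
  therapeutic protons.
* **Multiple Coulomb scattering**: the Gaussian (Highland) small-angle limit
  of Goudsmit-Saunderson theory. The Highland logarithmic correction is
  non-additive over sub-steps, so both engines evaluate it in *telescoped*
  form: the cumulative profile `G(t) = t (1 + log10(t/X0)/9)^2` is
  differenced over each step's water-equivalent thickness. A single step
  from the surface then reproduces the classic Highland formula exactly,
  while splitting a step into sub-steps conserves the angular variance by
  construction. No large-angle single-scattering tail is modeled; this is a
  deliberate fidelity reduction.
* **Nonelastic nuclear reactions**: a piecewise-linear macroscopic cross
  section in water (zero below 8 MeV, about 0.012/cm in the therapeutic
  range), scaled per material, with a fixed partition of the released
  energy: 55% to a secondary proton, 5% each to deuterons and alphas, 25% to
  neutrals (removed from the simulation), 10% to heavy recoils. Secondary
  emission is forward-peaked with density proportional to
  `exp(kappa cos theta)`, `kappa = 10`.
* **Absolute dose**: `protons_per_mu = 1e9` protons per monitor unit fixes
  the Gy scale for both engines; dose is reported as dose-to-water.

## The analytical pencil-beam engine

`compute_dose_apb()` implements the classical factorization: every spot
contributes `weight x IDD(WED(z)) x Gaussian(sigma(z))`, where

* the integrated depth dose (IDD, `bragg_idd()`) is built numerically from
  the shared physics: the CSDA depth-dose is mixed over a Gaussian range
  distribution (Bohr width), attenuated by nuclear survival, and augmented
  by the nuclear products (secondary protons spread Bragg-like over their
  projected residual range, short-ranged products deposited at the
  interaction depth, neutrals removed);
* the water-equivalent depth (WED) is raytraced **along the spot's central
  axis only** - the infinite-slab approximation. Heterogeneity that does not
  intersect the axis is invisible to the spot, which is precisely the
  failure mode the validation study probes;
* `sigma^2(z) = sigma_air^2 + sigma_MCS^2(z)` accumulates Fermi-Eyges
  moments of the Highland scattering power along the axis.

The optional nuclear-halo second Gaussian is off by default; the vendor
engine's halo model is proprietary and the study's observables do not
require it.

## The Monte Carlo engine

`mc_transport()` is a condensed-history Class II algorithm: hard nonelastic
interactions are sampled from the cross-section table; soft interactions
(ionization, scattering) are summarized per step. Specifics worth knowing:

* **Step control.** Steps are capped at a fraction (30%) of the residual
  range and at a per-voxel cap: one voxel near material interfaces and
  `open_step_mm` (default 6 mm, up to 12 mm in homogeneous water) deep
  inside single-material regions. Because the mean energy loss over a step
  is evaluated *exactly* through the closed-form range-energy map (not by an
  Euler step of `S(E)`), no maximum-fractional-energy-loss limit is needed
  for integration accuracy; the residual-range fraction alone controls how
  the Bragg peak is resolved. Deflections are applied at a midpoint hinge;
  deposits are apportioned to voxels by exact z-overlap so multi-voxel steps
  leave no depth-quantization pattern.
* **Delta electrons** are not transported: at therapeutic energies their
  range is below the 1-2 mm grids used here, so all ionization energy is
  deposited along the step. The transport cutoff is 1 MeV; below 10 MeV
  (residual range under 2 mm) the track ends with a straight CSDA segment.
* **Nuclear products.** The secondary proton continues under full Class II
  transport and may itself re-interact. Deuteron, alpha and heavy-recoil
  shares have (sub-)millimeter ranges and are tallied as an *expected-value*
  deposit along the travelled track (`P_interaction x 0.20 x E` per step)
  rather than as sampled point lumps; this is unbiased for the mean dose and
  removes the dominant rare-event variance, roughly halving the histories
  needed for a given statistical precision. Neutral energy is removed and
  tallied as escaped.
* **Range shifter.** Modeled purely as 75 mm of upstream water-equivalent
  thickness: the shifter slab is pre-transported (straggling and nuclear
  attenuation, nothing tallied), its scattering contribution is folded into
  the in-air spot sigma, and the Highland cumulative thickness starts at the
  shifter WET. The APB engine evaluates its IDD at `WET_shifter + WED(z)`,
  so the two engines stay consistent.
* **Statistics.** Histories are allocated per spot proportionally to weight
  (stratified; this removes inter-spot Poisson noise and keeps the tally
  working set cache-resident), with per-history RNG streams derived from the
  master seed so results are bit-reproducible under any execution order.
  Uncertainty uses the batch method: the run stops at the first batch (at
  least 10) where the mean relative standard error over voxels above 50% of
  the maximum dose falls below the target, 0.5% by default.
* **Energy ledger.** Injected = deposited + escaped is tracked in MeV; the
  expected-value nuclear tally makes the identity exact only in expectation,
  and runs of 1e5+ histories balance to well below 0.1%.

## Beam models and plans

The beamline (`beamline_config()`) carries the machine energy list (70-230
MeV in 0.5 MeV steps), the in-air spot sigma model
`sigma0(E) = 8 - 0.025 (E - 70)` mm plus 0.05 mm per mm of air gap when the
range shifter is in (no public machine data exists for the modeled nozzle;
the values are representative of a compact nozzle and chosen so the
beam-blur-to-geometry ratio of the desk-scale phantoms matches that of a
clinical field - they live entirely in the config), the 75-mm range shifter
WET and the 20-mm air gap.

`optimize_sobp()` builds the reference calibration beam: pristine-peak
layers spaced 3 mm in range across the modulation, per-layer weights from
nonnegative least squares against a flat central-axis plateau, lateral spot
lattices at 0.85 sigma spacing with 1D-NNLS edge enhancement, and a one-step
recalibration of the deepest layer so the distal 90% point lands on the
requested range within the 0.5-MeV energy granularity (about 1 mm of range).
The plateau is evaluated on `[range - modulation + 5, range - 5]` mm: the
distal 90% point *is* the start of the falloff, so the flat region
necessarily ends a few straggling widths before it.

`create_uniform_plan()` mirrors the heterogeneous-phantom planning trick:
the phantom's heterogeneity mask is overridden to water, layers are chosen
to cover the water-equivalent span of the target box over its full lateral
footprint, weights are optimized with the APB model only (the engines must
be compared on identical spot lists), and the override is then removed for
the final dose calculation - producing the deliberately nonuniform,
high-gradient distributions that make dose-engine errors visible.
`degrade_plan()` removes a seeded random fraction of spots or whole layers
to sharpen those gradients further.

## The virtual detector and the depth bookkeeping

`simulate_measurement()` emulates a 7-mm-pitch ionization-chamber array
with 6 mm of intrinsic water-equivalent buildup, cross-calibrated to
absolute dose: `d_m = 1.03 x stack + 6` mm for a solid-water stack, point
sampling of the dose cube at the effective plane (a 4-mm averaging kernel is
available but off by default, as the study does not model detector
response), a multiplicative calibration factor (default 1: the reference
SOBP plays the role of the TRS398 cross-calibration beam) and 1% Gaussian
channel noise. Planes read and write an OPG-style ASCII dialect documented
in `write_opg()`.

The depth conventions follow the clinical bookkeeping: `d_m` is the
water-equivalent depth below the solid-water surface, `d_e` the
corresponding expected geometric depth inside the dose cube (from the cube's
upstream face), and `d_gamma` the extraction depth giving best 2D gamma
agreement. "Best" is not defined by the original QA tools, so the package
fixes it: maximal pass rate at the analysis criterion, ties broken by
minimal mean gamma, then by proximity to `d_e`; the search scans plus/minus
5 mm in 0.1 mm steps by default.

## Gamma analysis

Global gamma throughout: the dose tolerance and the inclusion threshold are
percentages of the **maximum of the computed (evaluation) dose** - applied
to both the 2D and the 3D mode. (Whether the vendor's 3D tool normalizes to
computed or measured maximum is not documented; since the study's
measurement planes sit in high-dose regions the two differ by at most the
calibration error, and the package states its choice explicitly.) Thresholds
are 5% for 2D and 10% for 3D analyses; criteria 2%/2 mm, 3%/3 mm and
5%/3 mm. In 2D the measured plane is the reference (interpolated from the
7-mm pitch to a 2-mm grid) and the computed plane the evaluation; in 3D the
roles invert around the data: the sparse measured points are the reference
and the computed cube the evaluation.

The minimization searches a radius of 3 x DTA around each reference point,
sub-sampling the evaluation distribution to DTA/10 by bi/tri-linear
interpolation, visiting candidates in order of increasing distance so the
scan stops once the distance term alone exceeds the running minimum - which
makes the fast search *exactly* equal to a brute-force scan of the same
candidate lattice, a property the test suite asserts to 1e-9.

## The synthetic phantoms - and what they do not show

* `build_slab_phantom()`: layered water / solid-water stacks.
* `build_neck_analog()`: a soft-tissue cylinder (radius 35 mm) holding a
  cortical-bone annulus (4-7 mm) with an air cavity (2.5 mm) in its hollow,
  cut flat 18 mm past center and backed by 55 mm of solid water. This is a
  *motif* reproduction of an animal-neck phantom - discrete bone/air lateral
  heterogeneity upstream of a flat measurement stack - not anatomy. Bone
  defaults to density 1.85 g/cm^3, RSP 1.60 (typical cortical values, fully
  overridable); the geometry is tuned so a single anterior beam develops
  APB-versus-MC discrepancies in the >= 20% regime distal to the bone-air
  interface, the phenomenology reported for such interfaces.
* `build_breast_analog()`: a 45-mm water hemisphere on solid-water slabs;
  oblique incidence via `rotate_phantom()` (both engines transport along +z,
  so oblique beams resample the phantom into beam-eye-view on a
  nearest-neighbor grid).
* `hu_to_material()`: a 3-anchor piecewise-linear HU calibration (air at
  -1000, water at 0, cortical bone at 1500) for importing voxel volumes; the
  clinical CT calibration of the original study is not public, so this is a
  stand-in, not a reconstruction.

Because the physical measurements cannot be reproduced, the validation
pipeline sources its "measurements" from an independent high-statistics MC
run plus detector simulation. Pass rates produced this way validate the
*pipeline's sensitivity* - that the gamma machinery, depth search and
detector bookkeeping resolve real engine differences at the study's
tolerances - they are not re-derivations of the original measured pass
rates. Equally, agreement in these tests cannot certify either engine
against real tissue: the phantoms have no elemental-composition physics
(RSP and a nuclear scale factor summarize composition), no CT noise or
artifacts, and the detector model has no LET or recombination dependence.

## Problem sizes and numerical choices

All study conditions (depths 8/26/35 mm for the neck plans per the
measurement-depth table, 1% channel noise, criteria set, thresholds,
0.5% MC uncertainty rule) are fixed in the configs. Sizes chosen once for
desk scale, stated here as the package's own study design:

* Validation experiment: evaluated cubes on 1-mm grids, targets of
  20 x 24 mm laterally and 10 mm in depth in the solid-water stack,
  evaluated MC cubes at 4% relative uncertainty, measurement-source cubes
  on a 2-mm grid at 2.5% (after trilinear sampling the source noise is
  comparable to the 1% channel noise it feeds).
* The reference-beam Monte Carlo convergence run uses the full 250 mm /
  100 mm depth structure at a reduced 24 x 24 mm lateral field on a 2-mm
  grid with 12-mm open-region steps; the stopping-rule statistic is
  field-size independent.
* Depth searches: window 5 mm, step 0.1 mm, criterion 3%/3 mm; depths whose
  pass rate lies within 1 percentage point of the best (and mean gamma
  within 0.02 of the best among those) are statistical ties, resolved
  toward the expected depth - on flat-plateau planes the alternative is a
  noise-driven pick, and clinical tables show the expected depth there.
* Degenerate inputs: zero-thickness steps scatter nothing; rays missing the
  grid return WED 0 with a flag; empty gamma analyses (no points above
  threshold) are errors, not silent zeros; layer thicknesses that are not
  voxel multiples are assigned by dominant occupancy with a warning.

## Known limitations

Beyond the synthetic-data caveats above: the Gaussian scattering model has
no single-scatter tail, so extreme-angle halo effects are absent; the
nuclear energy partition is energy-independent; dose is dose-to-water by
construction (scaling deposits by 1/RSP), which differs from dose-to-medium
in bone by several percent - consistently for both engines, so cross-engine
comparisons are unaffected; and the APB engine carries no aperture or
sub-spot ("mini-beam") decomposition beyond the configurable N x N option.
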