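---
title: "Macrovascular transit time mapping from 4D-MRA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrovascular transit time mapping from 4D-MRA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matt4d)
```

## The measurement problem

Arterial-spin-labeling (ASL) based 4D magnetic resonance angiography
acquires one 3D inflow volume per labeling duration. Subtracting each label
image from its control image yields a difference volume that is non-zero
only where magnetically labelled arterial blood has arrived. As the label
duration grows (here 100--2200 ms over eight time points), the label bolus
fills progressively more distal vessels, so the per-voxel difference signal
stays at noise level until the bolus front arrives and then rises toward a
saturation plateau.

`matt4d` quantifies this by fitting, at every arterial voxel, a two-piece
saturation model

$$
f(t) = \begin{cases} 0 & t \le b \\ m\,\dfrac{t}{h + t} & t > b \end{cases}
$$

whose breakpoint $b$ is interpreted as the macrovascular arterial transit
time (mATT): the arrival time of the leading edge of the label bolus at
that voxel. $m$ is the saturation level and $h$ the half-rise time
($f = m/2$ at $t = h$ when $b = 0$).

### Two branch forms

The rise term can either keep its absolute time argument (`literal`,
above) or be shifted to start at the breakpoint (`continuous`):
$m\,(t-b)/(h + (t-b))$. Both are implemented in
`piecewise_saturation()` and selectable everywhere via `variant`.

The distinction matters for estimation. For the literal form, the model
values at the sampled times do not depend on $b$ except through the active
set $\{t_i > b\}$, so the residual sum of squares is piecewise constant in
$b$ between consecutive sample times: $b$ is only *interval*-identifiable,
and sub-sample recovery of a continuously distributed transit time is
impossible in principle. The continuous form identifies $b$ between
samples. `fit_voxel()` defaults to the literal form; the synthetic
generator and the end-to-end pipeline default to the continuous form, which
is the one whose recovery properties can be validated quantitatively.
Ties in the residual sum of squares across breakpoint candidates always
resolve to the smallest breakpoint (earliest arrival).

### The fitting algorithm

`fit_voxel()` profiles the problem: for each candidate breakpoint on a grid
(default 10 ms steps up to `b_max`), the amplitude has a closed-form
least-squares solution (clamped at zero) and the half-rise time is searched
on a log-spaced grid; the global best candidate is then polished by a
Levenberg--Marquardt refinement of all three parameters (for the literal
form only $m$ and $h$ are polished, since the objective is flat in $b$).
`b_max` defaults to the last label duration plus the final inter-sample gap
(2800 ms for the default schedule), because reported global maximum transit
times slightly exceed the last label duration, implying extrapolation past
the final sample is meaningful.

Voxels whose curve maximum stays below a noise floor are flagged
`below_noise` and excluded from maps. The automatic floor is
$2 \times 1.4826\,\mathrm{MAD}$ of the *unsmoothed* first-time-point
difference signal over the background ring adjacent to the vessel mask:
the detection threshold is a property of subtraction noise, so it is
estimated before smoothing (`fit_map(..., noise_reference = )`).

Identifiability limits are intrinsic to the eight-point schedule: a
breakpoint beyond 1200 ms leaves at most two rising samples for three
model parameters, and even in the 800--1200 ms gap the estimate rests on
three samples. Per-voxel estimates in that regime are noisy and biased
early; denser late sampling, not algorithmics, is the remedy.

## Vessel isolation

Fitting is restricted to arterial voxels by a filter cascade:
pairwise subtraction, brain masking, a temporal-maximum image (each vessel
at its brightest appearance), multi-scale 2D Frangi vesselness computed
slice-wise in the three cartesian planes, per-plane binarization at a
fraction (default 0.05) of each response's volume maximum, voxelwise
intersection of the three directional masks, morphological area opening,
and finally mask-guided joint bilateral smoothing of the difference series.

Numerical choices that required a decision:

* **Scale normalization.** Hessian entries are multiplied by
  $\sigma^\gamma$ with $\gamma = 1.5$ by default, the ridge-detection
  normalization for which a Gaussian ridge of profile sd $s$ responds
  maximally at scale $\sigma = s$; the classical $\gamma = 2$ (maximal
  response at $\sqrt{2}s$) is available. Matched-scale selection makes the
  `scales` parameter directly interpretable as expected vessel radii in
  pixels (default `c(1, 1.5, 2, 3)`).
* **Structureness scale `c`.** Three modes: a fixed value; `"auto"`, half
  the per-slice maximum Hessian norm; and `"auto-volume"`, half the
  volume-wide maximum. The per-slice mode adapts to slice-dependent signal
  but renormalizes *vessel-free* slices to pure noise, flooding the mask
  with noise components at realistic noise levels; the pipeline therefore
  defaults to `"auto-volume"`, which ties the structureness scale to the
  brightest vessels everywhere.
* **Blobness.** $\beta = 0.5$ (Frangi's convention). Because a
  feet-head-running vessel appears as a point in the axial plane, the
  three-plane intersection depends on vessels having an in-plane extent of
  a few voxels -- true for the large and medium cerebral arteries at
  angiographic resolution, and reproduced by the synthetic generator.
* **Area opening.** `min_size` (default 50 voxels, connectivity 26)
  removes blob-like components from pulsatility artifacts. Like the
  per-subject tuning it replaces, it should be set per dataset between the
  artifact-component and vessel-component sizes; the packaged synthetic
  studies use 200.
* **Smoothing.** The joint bilateral filter uses a spatial Gaussian with
  sd $= \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis (default FWHM
  $5\times5\times4$ voxels) and a range weight on the *binary vessel mask*
  (range sd 0.1), so vessel curves are averaged only along the vessel and
  never with background. Weights are renormalized per voxel: the filter is
  an exact identity on constants and can neither overshoot nor undershoot.
  The kernel extent in mm is the elementwise product of FWHM and voxel
  size (`kernel_extent_mm()`), chosen to approximate large-vessel
  diameters; smoothing visibly thickens vessels, which affects apparent
  blood volume but not arrival timing.

## Regional projection and statistics

`project_to_regions()` averages defined map voxels per atlas region
(unweighted arithmetic mean) and assigns the mean to every voxel of the
region; regions with fewer than `min_voxels` (default 5) fitted voxels stay
undefined. The voxel-count-weighted mean of the regional means equals the
global defined-voxel mean exactly, and projection is idempotent -- both are
enforced by tests. Registration is out of scope: the region-label volume
must already be on the native grid. For pre/post-vasodilation comparisons,
`regional_delta()` reports post $-$ pre (vasodilation $\to$ negative), and
`apply_common_mask()` restricts both maps to the voxels defined in the
pre-challenge analysis so that distal vessels becoming visible only after
vasodilation cannot masquerade as regional slowing.

`slice_profile()` and `fit_distance_regression()` summarize the map as
mean transit time versus caudal-cranial distance from the most caudal
slice and fit an unweighted ordinary least squares line, reporting the
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-2)$. Grouping slices (e.g. 3 per
entry) leaves the slope of a linear profile unchanged -- verified
analytically in the tests -- while stabilizing the per-entry means.
`roi_correlation()` regresses one regional parameter on another over
pairwise-complete regions (e.g. tissue transit time from multi-delay ASL
against macrovascular transit time) with the two-sided $p$ from the
$t$-distribution on $n-2$ degrees of freedom; no multiple-testing
correction is applied.

## The synthetic generator

No study data are distributable, so validation rests on
`generate_vessel_tree()` / `simulate_inflow_series()`, which emulate the
statistical structure the pipeline assumes:

* a branching tree grown by a seeded random walk from the most caudal
  slice with strong axial drift (lateral step probability 0.05 per axis),
  breakpoints $b = b_0 + g \cdot \mathrm{path\ length}$ increasing
  monotonically along every root-to-tip path (default inlet time 500 ms;
  gradient in ms per mm of path);
* a Gaussian vessel cross-section of radius 2 voxels (profile sd 1),
  because the three-plane Frangi intersection legitimately assumes vessels
  wider than one voxel;
* saturating inflow signal per voxel with additive white Gaussian noise
  inside the brain (no noise statistics are available for real subtraction images; SNR
  $= m_0/\sigma$ is reported with every acceptance run, default 10);
* a linear amplitude taper with distance (distal vessels fainter,
  mirroring the visibility limit on distal transit times) -- disabled in
  the quantitative-recovery fixtures, which take the per-voxel SNR
  condition literally;
* fluctuating ellipsoidal artifacts in the eight most caudal slices
  (high-variance subtraction residuals, as produced by tissue pulsatility
  near the circle of Willis), placed clear of the tree so that
  artifact and vessel components remain separable by size;
* a rectangular block parcellation (`generate_block_atlas()`) standing in
  for a fine anatomical atlas, and `simulate_tissue_att()`, which delays
  each brain voxel's nearest-vessel arrival time by a tissue delay plus
  noise to guarantee the positive macrovascular/tissue association the
  correlation analysis should recover.

Because transit time grows with *path length* while the slice profile
regresses on *caudal-cranial distance*, the realized slice-wise gradient
exceeds the configured per-path gradient by the mean tortuosity of the
walk (lateral steps plus branch-point jogs), about 10--12% under the
defaults; the per-voxel fit, conversely, slightly underestimates late
breakpoints. Recovered slice slopes carry both effects. What the generator deliberately omits:
MR physics (label T1 decay, labeling efficiency, keyhole/view-sharing
artifacts), flow velocity profiles, motion, and spatially correlated
reconstruction noise. Passing recovery tests therefore demonstrate the
estimator and cascade under the stated statistical assumptions, not
robustness to scanner physics.

## Validation study sizes

The packaged studies use $64^3$ voxel volumes (1 mm isotropic) at SNR 10
with caudal-cranial gradients 7.7 and 6.6 ms/mm -- the published pre/post
vasodilation pair -- recovering both slopes within a few percent with
adjusted $R^2 \approx 0.98$ and their difference well within 0.5 ms/mm;
breakpoint recovery is exact (sub-ms) without noise and has RMSE below
100 ms at SNR 10 on 500 vessel voxels after mask-guided smoothing. The
component-labeling and breakpoint searches are validated against
independent oracles (an igraph-based component count and an exhaustive
1 ms grid). All runs are seeded; `scripts/acceptance.R` re-derives every
number from scratch.

## Known limitations

* Transit times beyond $\sim$1200 ms are weakly identified under the
  eight-point schedule (see above); the fitted upper bound `b_max` admits
  values up to 2800 ms but their variance is large.
* The regional mean weights through-passing and terminal vessels equally;
  no correction is attempted.
* The literal branch form cannot localize breakpoints between samples;
  use the continuous form when sub-sample resolution matters.
* Motion is not modelled or corrected; severely motion-corrupted series
  should be excluded upstream.
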