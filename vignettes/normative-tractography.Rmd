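---
title: "Normative tractographic atlases and lesion scoring: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative tractographic atlases and lesion scoring: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntatlas)
```

## The model

The package models VIM-targeted lesion scoring as a three-stage pipeline.

**Per-subject connectivity.** For a reference subject with an orientation
field (up to two unit fibre directions per voxel, mixture weights, and a
von Mises–Fisher angular concentration κ), the tracker launches
`samples_per_seed_voxel` streamlines from every voxel of the VIM seed ROI
and records the fraction that reach the precentral terminus ROI. The
resulting hit-fraction map lives in [0, 1] and is zero off the seed.

**Atlas.** Each subject's map is pull-resampled to the template grid
through that subject's known template-to-subject transform (template voxels
outside a subject's support contribute 0 — unreached territory means no
connectivity, and dropping those voxels instead would bias the median
upward at the atlas rim). The voxelwise median across subjects is divided
by its single global maximum, so the atlas spans [0, 1] with maximum
exactly 1. We read the normalization as one global maximum per atlas
object (the atlas is built per hemisphere); per-slice normalization would
not give a [0, 1] object. With an even subject count the median is the
midpoint of the two central order statistics.

**Patient fit and NTC.** The atlas is warped (trilinear) onto the
patient's preoperative grid — preop T1 is the common frame, and the
postoperative lesion mask is moved to it by a rigid transform with
nearest-neighbour resampling, never the reverse. The NTC is the arithmetic
mean of the patient-fit atlas over the lesion voxels, with atlas values
looked up at voxel centres (no sub-voxel averaging within a lesion voxel).
Lesion voxels falling outside the atlas support contribute 0, which is
what makes a fully non-overlapping lesion score exactly 0. Lesion volume
is computed in the mask's native grid before any resampling; when a
transform is applied both native and coregistered volumes are available to
the caller.

## Geometry conventions

World space is RAS in millimetres; voxel indices are 0-based; a voxel's
world position is its centre (NIfTI-1 convention, which avoids half-voxel
ambiguity). Resampling is pull-style: each target voxel centre is mapped
through the inverse of the source-to-target transform and interpolated in
the source; out-of-support locations yield 0, not NaN. Masks are resampled
with nearest neighbour only, so they stay binary. Displacement-field
transforms store world-mm displacement vectors on a grid; the inverse of
x → x + u(x) is computed by fixed-point iteration y ← x − u(y) to
10⁻³ mm within 50 sweeps, and non-convergence is an error rather than a
warning — a silent bad inverse would corrupt every downstream volume.

## Tracker parameters and choices

| parameter | default | meaning |
|---|---|---|
| `step_mm` | 0.5 | Euler step length (mm) |
| `max_steps` | 2000 | cap per streamline |
| `curvature_limit_deg` | 80 | max per-step turn |
| `samples_per_seed_voxel` | 100 | streamlines per seed voxel |
| `jitter` | TRUE | uniform launch position within the seed voxel |
| `bidirectional` | FALSE | explore both initial orientations |

Fibre lookup is nearest-voxel with no directional interpolation: this
keeps the κ = ∞ tracker exactly checkable against a voxel-graph
reachability oracle. Launch positions are jittered uniformly within the
seed voxel to remove grid artifacts; centre launches (`jitter = FALSE`)
are available for deterministic checks. By default a seed fires one random
initial sign along the sampled fibre; the `bidirectional` switch explores
both orientations and is used wherever a reachability semantics is wanted
(a directed fibre tube is only traversed to the terminus from one of the
two orientations, so {0, 1} agreement with graph reachability — and hit
fraction 1 inside a dispersion-free tube — require exploring both).

Every streamline draws from its own counter-based substream seeded by
(base seed, seed-voxel rank, sample, branch). Runs are therefore
bit-identical for a fixed seed, and growing the terminus ROI can only
truncate a trajectory, never alter it — hit fractions are monotone
non-decreasing in the terminus under common random numbers, which the test
suite exercises directly.

## Atlas targeting

`medial_apex()` returns, among voxels at or above `hot_fraction` (default
0.9, configurable — no published threshold exists for "hottest voxels")
times the atlas maximum, the voxel most medial in world x, breaking ties
by most anterior then most superior. Clinically the medial edge of the
hotspot, not its centre of mass, is the preferred sonication target
because ultrasonic energy spreads predominantly inferoanteriolaterally;
targeting the centre risks dosing the internal capsule. The AC–PC helper
`stereotactic_target()` implements the indirect rule (11 mm lateral to the
third-ventricle wall, ¼ AC–PC distance anterior to PC, 2 mm superior).
An AC–PC pair alone does not fix the sagittal plane, so the function takes
a superior-direction hint (default world +z); supplying a rotated hint
makes the construction exactly equivariant under frame rotations.

## Cohort statistics

ROC curves sweep cutoffs at midpoints between consecutive observed values
(midpoints are estimator-stable and match the convention of reporting
directional cutoffs such as "< 127.4"), classifying strictly in the
favorable direction; AUC is the trapezoid area, which equals the
Mann–Whitney rank statistic with half credit for ties. The
Youden-optimal cutoff maximises J = sensitivity + specificity − 1, with
ties broken by higher specificity and then by the more extreme cutoff.
Operating-cutoff classification (`classify_by_cutoffs()`) is strict:
values exactly at 127.4 mm³, 0.0594 cc or 0.544 are unfavorable.

Group comparisons use the tie-corrected Kruskal–Wallis H with a χ²
approximation. The convention of appending a small group's mean to reach
a minimum group size is available behind `pad_to` but off by default:
padding manufactures data and must be an explicit analyst decision. The
2×2 association test is Fisher's exact test (two-sided, hypergeometric
sum); where a published two-group p-value does not name its test, Fisher
is this package's declared choice. Analyses are complete-case per
variable, with per-analysis n reported.

## The synthetic generator

The phantom emulates, at desk scale, the features the pipeline actually
exercises: a VIM-like seed ellipsoid (radii 5–6 mm) connected to a
precentral-like terminus slab by a laterally bowed quadratic-Bezier fibre
tube (radius 5 mm) on a 2 mm, 28×32×40 right-hemisphere window; subject
anatomy generated by carrying the template geometry through a small random
affine (≤ 2° rotation, ±3 % scale, ≤ 3 mm shift) composed with a smooth
sinusoidal displacement field (amplitude ≤ 1.5 mm, wavelength 60 mm). Two
numerical details matter. First, sampled displacement fields are tapered
smoothly to zero within four voxels of the field border; an abrupt edge
would locally break the contraction property the fixed-point inverse
relies on. Second, fibre directions near the tube rim are bent slightly
toward the centerline (a (d/R)²-weighted centripetal term, 0.6 maximum):
pure tangents let rim streamlines drift out of a curved tube, whereas the
corrected field keeps every centre-launched seed voxel connected, matching
the geometric intent of the phantom.

Because the subject transforms are known analytically, warping hotspots
back to the template is free of registration error — deliberately so, to
keep registration quality out of what the tests measure. The phantoms do
not emulate real diffusion data: no noise floor, no crossing-fibre
ambiguity beyond the two-fibre mixture, no registration failure, no
partial-volume effects at ROI edges. Passing tests therefore validate the
pipeline's algebra and contracts, not its behaviour on clinical images.

The cohort generator places ellipsoidal lesions (log-normal volume,
median 120 mm³, σ_log = 0.45; mild 1.15 : 1 : 0.87 anisotropy) with
1.5 mm Gaussian jitter around the patient-space atlas apex, computes each
patient's NTC through the real patient-fitting code path on a 1 mm,
37³ patient window, and draws outcomes with the reported effect
directions: the log-odds of a "worse" QoL rating jump by 2.4 above the
127.4 mm³ volume threshold (plus a mild 0.003/mm³ smooth slope) and fall
with NTC (−3 per unit); ADV is 0.47 × lesion volume (cc) plus noise;
subjective tremor suppression is drawn per QoL category with means
86.8 / 46.7 / 93.2 % (better / same / worse); adverse-effect propensity
rises with volume and falls with NTC around the reported per-AE base
rates. Intercepts were chosen so the category mix approximates the
reported 62 / 23 / 15 % split. All stages draw named substreams from one
base seed, so any stage is reproducible in isolation and a fixed seed
yields a byte-identical cohort CSV.

## Problem sizes

The bundled checks run atlas banks of 5–20 subjects at 2 mm resolution
(the default desk-scale bank is 20; the atlas construction itself is
size-agnostic), cohorts of up to 500 patients, and tracker oracles on
grids up to 20×20×36. These sizes keep the full suite around two minutes
while leaving every code path exercised end to end.

## Known limitations

* The tracker is a simplified Euler sampler: no anatomical constraints, no
  distance correction, no fibre-model fitting from diffusion-weighted
  data; orientation fields are inputs.
* Registration is taken as given (known or estimated elsewhere); the
  package estimates rigid landmark transforms only.
* The published cohort's raw data are not redistributable, so cohort-level
  statistics are validated on simulated cohorts with known structure, not
  against the published AUC/H/R² values.
* NIfTI stores affines as float32; affines with entries not representable
  in single precision round-trip only to float32 precision.
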