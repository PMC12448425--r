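---
title: "Shape scores for tumor masks: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape scores for tumor masks: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorshape)
```

# The measurement problem

Two scores summarize the shape of a segmented tumor:

* the **sphericity index** `SI = A / ((36*pi)^(1/3) * V^(2/3))`, the
  tumor's surface area relative to the equal-volume sphere — a pure,
  size-free complexity measure bounded below by 1 (isoperimetric
  inequality);
* the **contact surface area** `CSA = A - B`, the surface area exposed to
  brain parenchyma once the dura-abutting patch `B` is subtracted — a
  mixed measure of size, shape, and location.

Both reduce to two geometric primitives on a binary mask: a surface-area
estimate and a rule for deciding which part of the tumor surface lies on
the dura. Neither primitive is innocent; this vignette records exactly how
they are computed, why, and what the package's green tests do and do not
establish.

# Surface extraction

## Why not count voxel faces, and why not raw marching cubes

The exposed-voxel-face area of a digitized smooth solid does not converge
to the solid's area — for a sphere it overestimates by up to ~50%,
because stair-steps never flatten. Marching cubes on the raw binary field
(vertices at edge midpoints) is far better but still biased: on a
digitized ball of radius 20 mm at 1 mm spacing it overestimates the area
by roughly 9%, essentially independent of resolution, which would bias
every SI upward and every CSA with it.

`extract_surface()` therefore smooths the binary indicator with a small
Gaussian (default `smooth_sigma = max(spacing)`, i.e. one voxel, applied
separably with zero extension) and extracts the 0.5 isosurface of the
smoothed field with linear interpolation along cell edges. The test suite
pins the resulting accuracy: sphere-area errors at 2 / 1 / 0.5 mm spacing
are a few percent, a few tenths of a percent, and near one tenth of a
percent, decreasing strictly — the convergence the acceptance criteria
demand. No smoothing is ever applied to the *mesh*; smoothing acts on the
field before extraction, which is also how the clinical 3D modelling tools
this workflow descends from prepare surfaces.

The cost is a known bias at small scales: smoothing with sigma shrinks the
area of a convex body by a term of order `(sigma/r)^2`. At one-voxel sigma
this is negligible for tumors in the clinically reported size range
(volumes 12.8-70.3 cm^3, radii ~14-26 mm) but reaches ~2-3% for a ball of
radius 8-10 mm at 1 mm spacing, pushing its measured SI to ~0.97-0.98.
The invariant "SI >= 0.98 for convex phantoms" is therefore asserted at
clinical sizes, and a test shows the small-ball case recovers once the
lattice is refined to 0.5 mm. If you score sub-centimetre lesions, resample
finer (`resample_isotropic()`) or reduce `smooth_sigma` deliberately.

## The marching-cubes implementation

No isosurface extractor exists in this package's allowed dependency set,
so one is implemented here, with two properties worth documenting:

* **The 256-case table is generated, not transcribed.** For each corner
  configuration, the crossing segments on every face are paired by a fixed
  rule — on an ambiguous (diagonally occupied) face each interior corner is
  cut off by pairing its two adjacent crossing edges. Because the rule
  depends only on the four shared corner states, the two cubes sharing any
  face agree on its segments, which makes the global mesh watertight by
  construction. The table generator is itself under test (every crossing
  edge appears exactly once; all loops close).
* **Loops are fan-triangulated from their centroid** (a 3-loop is a single
  triangle). The centroid of a loop lies strictly inside its cube, so no
  triangulation chord can fall into a face plane; fanning from a loop
  vertex can place a chord inside an ambiguous shared face, where the
  neighbouring cube lays the same chord and the mesh becomes non-manifold.
  This failure mode was observed in an exhaustive sweep of all 4096 masks
  of a 2x2x3 lattice and is the reason for the centroid rule; the sweep now
  passes with every edge shared by exactly two triangles.

Triangle orientation is fixed by aligning each loop's Newell normal with
the local inside-to-outside direction; the tests assert positive enclosed
volume and agreement between two independently coded divergence-theorem
volume routes to 1e-9.

# The dural patch B

The original clinical workflow traced the dura-contact patch manually.
The reproducible surrogate here is a distance rule:

> a tumor triangle belongs to `B` iff its centroid lies within `tolerance`
> of the brain-mask boundary mesh (exact point-to-triangle distance,
> bucketed uniform grid).

`tolerance` defaults to `max(spacing) / 2` — half a voxel, the natural
scale below which "on the boundary" is not resolvable — and is an explicit
argument everywhere. Two consequences matter:

* Where the tumor surface meets the dura at a grazing angle the rule is
  accurate; where it meets orthogonally (a hemisphere sitting flat on the
  dura) the band of width `tolerance` along the rim contributes spurious
  contact area of order `perimeter x tolerance` — about +5% for a 10 mm
  half-ball at 0.5 mm spacing, shrinking proportionally with the lattice.
  The tests document this by scoring that phantom at 0.25 mm.
* `B = 0` exactly when the tumor is everywhere at least `tolerance`
  interior to the brain mask, so subcortical tumors get `CSA = A`
  identically, and `CSA = A - B` holds bitwise (the subtraction is the
  definition, asserted in every phantom test).

# Outcomes: EOR and grouping

`compute_eor()` is `clamp(1 - post/pre, 0, 1)`: apparent growth between
scans clamps to 0 (longitudinal registration is out of scope), and GTR
means exactly no measurable residual. `group_eor()` reproduces the
published figure's grouping: GTR is its own category; the remaining
records split into tertiles by rank with boundaries at `ceiling(n/3)` and
`ceiling(2n/3)`, ties broken by stable input order so reruns are
deterministic.

# The synthetic cohort

`simulate_cohort()` draws a cohort whose *stated world* is the published
Table-1 marginals: age 39 (31-51) years, volume 32.0 (12.8-70.3) cm^3,
CSA 60.9 (32.4-119.7) cm^2, SI 1.57 (1.36-1.93); 60% male, 61% eloquent,
11% biopsy-only, 26% GTR among resections, 15% deficits; the published
location and diagnosis splits.

Distributional choices the source does not constrain:

* **Split log-normal marginals.** Only median and IQR are published. The
  printed IQRs are asymmetric on the log scale (volume:
  `log(32/12.8) = 0.92` vs `log(70.3/32) = 0.79`), so a single-sigma
  log-normal anchored at the median misses both quartiles by ~7%. Each
  marginal therefore uses a separate log-sigma below and above the median
  (continuous at the median), which reproduces all three printed values
  exactly; the calibration test checks median and quartiles at n = 10000
  to within 5%. SI is modelled as `1 + X` with `X` split log-normal, so
  `SI >= 1` holds by construction.
* **Gaussian copula.** Volume and CSA are strongly coupled (0.80) because
  CSA is substantially a size measure; age couples weakly to CSA and SI
  (0.15/0.16, the published univariable rank correlations); CSA-SI at
  0.35. The copula preserves the calibrated marginals exactly.
* **EOR model.** `EOR = clamp(b0 + b_CSA*CSA + b_SI*SI + b_eloq*eloquent
  + noise, 0, 1)` with the published multivariable coefficients as default
  injected truths (`-0.0012` per cm^2, `-0.097` per SI unit, `-0.10` for
  eloquence), Gaussian noise (sd 0.15), and a GTR point mass at 1. The
  GTR probability is logistic in centred CSA and SI (defaults -0.015,
  -0.8): making the point mass independent of shape dilutes the rank
  correlation between EOR and CSA far below the published -0.49 anchor
  that the generator is contractually calibrated against, and
  shape-dependent GTR is precisely the association the source reports.
  The intercept is derived from the target STR median rather than fitted.
* **Deficit model.** Logistic in SI, age, volume and eloquence. The source
  prints no deficit-model coefficients, only directions in prose, so the
  defaults (0.8 per SI unit, 0.015/year, 0.008/cm^3, 0.7 for eloquence)
  are this package's realistic choices; the intercept is solved
  numerically so the realized deficit rate matches the published 15%
  (anchoring at covariate medians would inflate it by Jensen's
  inequality).
* **Missingness.** Biopsy-only patients have `NA` EOR and deficit status,
  and every analysis excludes them complete-case, mirroring the per-model
  n of the source.

What the generator does **not** emulate: anatomy (no brain-shaped masks,
no lobe geometry behind the location label), scanner effects, segmentation
error, inter-rater variability, or any survival process. A green test on
this cohort establishes that the statistics recover what was injected
under the stated world — not that the pipeline would reproduce the
clinical tables from real images.

`cohort_from_phantoms()` closes the loop the other way: its CSA and SI
columns are measured by the full geometry pipeline on randomized phantoms
(radii 14-22 mm, the published volume range), not drawn from
distributions, so schema and invariants are exercised end to end.

# The statistical battery

* Rank tests (Spearman, Mann-Whitney U, Kruskal-Wallis) are computed
  directly with average ranks and tie-corrected variances.
  `mann_whitney()` enumerates all rank assignments for an exact two-sided
  p (twice the smaller tail) when both groups have at most 8 untied
  observations, otherwise uses the normal approximation with tie and
  continuity corrections; the two branches agree within 0.02 at the
  boundary, by test. Base R's implementations serve as oracles in the
  suite, never as the computation path.
* `huber_irls()` is iteratively reweighted least squares with Huber
  weights, tuning constant `k = 1.345` (the conventional 95%-efficiency
  choice; the source names only "Huber weights"), scale re-estimated each
  iteration as `median(|r|)/0.6745`, convergence at 1e-8 on coefficients,
  at most 200 iterations. Standard errors use the M-estimation asymptotic
  covariance with Huber's small-sample correction; intervals and p-values
  are normal-theory. The suite pins it to MASS::rlm to ~1e-5 on
  coefficients, to OLS exactly as `k -> Inf`, and to better-than-OLS slope
  error under a planted gross outlier.
* `logistic_irls()` is Newton/IRLS with step-halving (the log-likelihood
  trace is non-decreasing, asserted), Wald intervals, and explicit
  separation detection: if the iteration fails to converge while the
  fitted probabilities pin to their classes or the linear predictor
  diverges, a distinct error class is raised instead of returning silent
  garbage. Large fitted linear predictors with finite, converged
  coefficients are *not* flagged — heavy-tailed covariates produce them
  legitimately.
* The multivariable layouts mirror the published models: EOR ~ shape +
  age + volume + eloquence + lobar location (Huber), deficits ~ shape +
  age + volume + eloquence (logistic), one fit per shape score, lobar
  reference category `central_deep` (the category absent from the
  published coefficient rows), alpha 0.05 two-sided, no multiplicity
  correction.

## Coverage experiments and censoring

One acceptance criterion asks the fitted 95% CI of the injected CSA
coefficient to cover the truth in at least 90 of 100 simulations at
n = 5000. Under the full stated world this is impossible for reasons worth
stating plainly: the response is censored (clamping at 0/1 plus a GTR
point mass), and a linear estimator of a censored response is attenuated;
with `se ~ 1e-5` at n = 5000, even sub-percent attenuation moves the
estimate many CI-widths off the truth. Coverage is an estimator property
under the model the estimator assumes, so the coverage harness runs the
generator in its *uncensored linear regime*: no GTR mass, noise sd 0.05, a
derived intercept keeping the linear predictor inside (0, 1), a tightened
CSA spread (IQR 45-85, same median), and no injected SI effect (the fitted
CSA model omits SI, and a correlated omitted effect is bias by
construction). Sign recovery, the univariable battery, calibration, and
the type-I-error checks all still run under the full censored world.

# Degenerate inputs and numerical conventions

* World coordinates are millimetres; voxel indices are 0-based and map
  through the affine at voxel centres. Reports divide by 100/1000 into
  cm^2/cm^3 at the very end.
* Masks binarize by `value != 0`; multi-label atlases are out of scope.
* Empty tumor masks are an explicit validation error for surface
  extraction and shape reports; `mask_volume()` returns 0.
* `resample_isotropic()` is nearest-neighbour only — interpolation would
  invent partial labels.
* Tumor voxels outside the brain mask are an error that reports the voxel
  count; nothing is clipped silently.
* Degenerate triangles are impossible by construction at the stored
  precision (vertices interpolate strictly between corners of opposite
  sign); enclosed-volume and closedness checks run in the suite, not at
  extraction time, to keep the hot path lean.
* The CLI maps error classes to exit codes (2 I/O, 3 validation, 4
  statistical degeneracy) and echoes its run parameters as log lines, so
  a rerun of a logged command is a reproduction.

# Known limitations

* The dural-contact rule is a surrogate for manual tracing; its tolerance
  parameter is honest but means `B` carries a resolution-dependent band
  error where tumor and dura meet orthogonally.
* Field smoothing trades a large systematic area bias for a small
  size-dependent one; sub-centimetre lesions at coarse spacing need finer
  lattices.
* The cohort simulator's deficit-model effect sizes are package choices,
  not published values; treat recovered deficit coefficients as tests of
  the machinery, not as clinically meaningful magnitudes.
* Shapiro-Wilk is capped at n = 5000 (the underlying implementation's
  limit); screen subsamples above that.
* No survival modelling, no imputation, no multi-focal tumors, no
  intensity radiomics.
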