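# tumorshape

Shape scoring and outcome modelling for brain-tumor segmentation masks.

In diffuse low-grade glioma (LGG), how *round* a tumor is and how much of
its surface actually touches brain parenchyma appear to matter for surgery:
surgeons achieve lower extents of resection on complexly shaped tumors, and
shape complexity may predict new focal deficits. `tumorshape` implements the
two shape scores behind that line of work, the simulators needed to test
them without patient data, and the accompanying statistical battery:

* **Sphericity index (SI)** — the ratio of the tumor's surface area to the
  surface area of a sphere of equal volume,

  `SI = A / ((36*pi)^(1/3) * V^(2/3))`,

  which is 1 for a perfect sphere and grows with shape complexity,
  independent of size.
* **Contact surface area (CSA)** — the tumor surface exposed to brain
  parenchyma: `CSA = A - B`, where `A` is the total tumor surface area and
  `B` the part of the surface abutting the dura mater. For a subcortical
  tumor `B = 0` and `CSA = A`.
* **Extent of resection (EOR)** — the fractional decrease in measurable
  tumor volume from pre- to postoperative MRI, `1 - V_post / V_pre`,
  clamped to `[0, 1]`, with gross total resection (GTR) meaning no
  measurable residual (`EOR = 1`).

Who it is for: image-analysis and clinical-research groups who have
co-registered binary tumor and brain (dura-enclosed region) masks in NIfTI
format and want reproducible shape scores, plus methodologists who want a
fully synthetic, seeded test bed for shape--outcome association studies.

## What is inside

| Layer | Functions |
|---|---|
| Mask I/O | `read_mask()`, `write_mask()`, `validate_pair()`, `resample_isotropic()` (NIfTI-1/2, gzipped or not; no external NIfTI dependency) |
| Geometry | `extract_surface()` (built-in watertight marching cubes on a lightly smoothed indicator field), `mesh_area()`, `mesh_enclosed_volume()`, `dural_contact_area()`, `compute_shape_report()` |
| Outcomes | `compute_eor()`, `group_eor()` (GTR + three STR tertiles) |
| Simulators | `make_phantom()` (balls, spheroids, cubes, lobulated and dura-clipped balls with closed-form oracles), `simulate_cohort()`, `cohort_from_phantoms()` |
| Statistics | `shapiro_screen()`, `spearman_rank()`, `mann_whitney()` (exact + tie-corrected asymptotic), `kruskal_wallis()`, `huber_irls()`/`huber_fit()` (robust EOR models), `logistic_irls()`/`logistic_fit()` (focal-deficit models), `run_univariable_battery()`, `run_multivariable_models()`, `eor_group_summary()` |
| CLI | `tumorshape_cli()` with `shape`, `simulate`, `analyze` subcommands (wrapper script in `inst/cli/tumorshape`) |

## Worked example

A ball of radius 10 mm whose centre sits 5 mm inside the dura (so the dura
clips it to a spherical cap) has closed-form contact areas: the dural patch
is the disc `pi*(r^2 - d^2) = 235.6 mm^2` and the CSA is the spherical zone
`2*pi*r*(r + d) = 942.5 mm^2`.

```r
library(tumorshape)

ph <- make_phantom(phantom_spec("clipped_ball", radius = 10, clip_depth = 5,
                                spacing = 0.5))
compute_shape_report(ph$pair, id = "demo")
#> <shape_report demo>
#>   volume      3.54 cm^3
#>   A          11.65 cm^2
#>   B           2.34 cm^2
#>   CSA         9.31 cm^2
#>   SI        1.0374
```

`B = 2.34 cm^2` and `CSA = 9.31 cm^2` sit within ~1% of the oracles above;
`SI = 1.037` correctly reports a near-spherical solid. The same pipeline
runs from NIfTI files via `read_mask()` + `validate_pair()`, or from the
command line:

```sh
inst/cli/tumorshape shape --tumor tumor.nii.gz --brain brain.nii.gz --out report/
```

A fully synthetic cohort with the published marginal structure (age median
39, volume 32.0 cm^3, CSA 60.9 cm^2, SI 1.57, 26% GTR, 15% deficits) and
injected shape-outcome effects:

```r
co <- simulate_cohort(cohort_spec(n_patients = 225, seed = 1))
bat <- run_univariable_battery(co)
bat[bat$variable == "eor", c("metric", "estimate", "p_value", "significant", "n")]
#>   metric estimate  p_value significant   n
#>      csa   -0.478 5.78e-13        TRUE 203
#>       si   -0.325 2.19e-06        TRUE 203
```

Both rank correlations recover the injected negative shape-EOR effects
(the anchors are -0.49 and -0.38). The multivariable robust model recovers
the injected CSA slope:

```r
fits <- run_multivariable_models(co)
subset(fits$eor_csa$coefficients, term == "CSA")
#>   term estimate       se ci_lower ci_upper  p_value
#>    CSA -0.00154 0.000177 -0.00189  -0.0012 3.16e-18
```

i.e. each additional cm^2 of contact surface lowers the expected EOR by
~0.0015 in this draw (injected truth -0.0012, inside the CI). The
boxplot-style EOR grouping shows the same gradient:

```r
eor_group_summary(co)[, c("group", "n", "csa_median", "si_median")]
#>        group  n csa_median si_median
#>    STR-lower 47      148.2      1.80
#>   STR-middle 47       69.7      1.53
#>    STR-upper 47       48.8      1.46
#>          GTR 62       40.9      1.45
```

## Notes

* All internal geometry is in millimetres; reports use cm^2 / cm^3.
* Surface extraction smooths the binary field by one voxel (Gaussian)
  before taking the 0.5 isosurface; this is what keeps sphere-area errors
  below 1% where raw binary marching cubes errs by ~9%. See the methods
  vignette (`vignettes/shape-metrics.Rmd`) for all numerical choices and
  their limitations.
* The dural patch `B` is defined by a point-to-mesh distance rule with an
  explicit tolerance (default half the largest voxel spacing) — a
  reproducible surrogate for the manual tracing used in the original
  clinical workflow.
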