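# lesiondir

Directional analysis of white-matter lesions in 3D MRI: which way do
lesions point, which way do they grow, and does either follow the brain's
anatomy?

Multiple sclerosis lesions form around small veins and evolve under
several competing anatomical influences: the local white-matter fibre
bundles, CSF-related "surface-in" gradients emanating from the
ventricular surface, and the veins themselves. `lesiondir` quantifies
these influences per lesion from co-registered NIfTI volumes:

- **Shape**: each lesion is summarized as a solid ellipsoid via the
  eigen-decomposition of the second central moment matrix of its voxel
  centres (world mm). The principal eigenvector ε₁ is the lesion major
  axis; axis lengths follow λᵢ = 2·√(5·mᵢ); shape anisotropy is the
  fractional-anisotropy-style scalar
  FA = √½·√[((λ₁−λ₂)² + (λ₂−λ₃)² + (λ₃−λ₁)²) / (λ₁²+λ₂²+λ₃²)] ∈ [0, 1].
- **Reference axes** per lesion: the surface-in gradient **g**
  (normalized gradient of the Euclidean distance transform from the
  ventricle mask), the dominant tract direction **w** (principal
  eigenvector of the sign-free dyadic tensor Σuuᵀ of the DTI primary
  eigenvectors inside the lesion), the vein axis **v** (principal moment
  axis of the vein voxels intersecting the lesion), and an
  orthogonal-to-vein axis **v90** (projection of ε₁ onto the plane ⊥ v).
- **Orientation taxonomy**: a lesion is attributed to every feature whose
  axis lies strictly within 45° of ε₁ (axial angle,
  cos θ = |a·b|/(|a||b|)), giving 11 categories (G, W, V, V90, GW, GV,
  WV, GWV, GV90, WV90, GWV90) plus NONE; lesions without a measurable
  vein are excluded rather than misfiled. The chance of aligning with one
  fixed axis under a uniformly random orientation is the spherical-cap
  fraction 1 − cos 45° ≈ 29%; per-lesion joint chance probabilities over
  all categories are estimated by seeded Monte-Carlo against the lesion's
  actual axis geometry.
- **Longitudinal change**: MTR maps ((MToff − MTon)/MToff × 100, pu),
  voxelwise Jacobian determinants det(I + ∇u) of the baseline→follow-up
  displacement field, cohort ±1 SD classification into
  expanding/stable/contracting, a magnitude-weighted orientation-tensor
  estimate of the major axis of expansion, and per-lesion ΔMTR.
- **Cohort summaries**: per-patient category proportions (patients
  weighted equally), exact binomial observed-vs-chance tests with
  broom-style `tidy()`/`glance()`, and unadjusted ΔMTR-by-arm tables.

Because clinical trial MRI of this kind is rarely shareable, the package
ships a first-class synthetic phantom generator (`phantom_spec()`,
`build_phantom()`, `sample_cohort()`) that emulates all required inputs —
labelled lesions, ventricle and vein masks, tract fields, MT pairs at two
timepoints, analytic deformation fields — with exact ground truth, so the
entire pipeline is testable end to end.

## Worked example

```r
library(lesiondir)

spec <- phantom_spec(n_lesions = 3, categories = c("V", "WV", "EXCLUDED"),
                     dynamics = c("expanding", "stable", "stable"),
                     delta_mtr = c(0.5, 0, 0), seed = 42)
phantom <- build_phantom(spec)
result  <- analyze_phantom(phantom)
result[, c("lesion_id", "category", "excluded", "angle_v_deg",
           "anisotropy", "mean_jacobian", "delta_mtr")]
#> # A tibble: 3 × 7
#>   lesion_id category excluded angle_v_deg anisotropy mean_jacobian delta_mtr
#>       <int> <fct>    <lgl>          <dbl>      <dbl>         <dbl>     <dbl>
#> 1         1 V        FALSE          1.60       0.550          1.08       0.5
#> 2         2 WV       FALSE          0.209      0.577          1          0
#> 3         3 <NA>     TRUE          NA          0.598          1          0
```

Lesion 1 was generated lying along its central vein with an 8% volume
increase and a +0.5 pu MTR rise over the interval: the pipeline measures
its major axis 1.6° from the vein axis (category V), a lesion-mean
Jacobian of exactly 1.08, and recovers the injected ΔMTR. Lesion 3 has no
vein in reach, so it is excluded from vein-dependent classification
instead of being forced into a category.

The chance model and an observed-vs-chance comparison:

```r
chance_single(45)
#> [1] 0.2928932

tidy(observed_vs_chance(33, 100, chance_single(45), category = "V"))
#>   category estimate  expected successes   n direction   p.value ...
#> 1        V     0.33 0.2928932        33 100      more 0.4418235 ...
```

33/100 vein-aligned lesions is direction "more" than the 29.3% chance
expectation but far from significant at that sample size.

For clinical-style data on disk, `run_pipeline("config.yaml")` reads the
declared NIfTI inputs, runs every stage whose inputs are present, and
writes `lesion_shape.csv`, `feature_axes.csv`, `orientation.csv` and
`dynamics.csv` (see `?run_pipeline` for the config layout).
`analyze_cohort()` pools patients, applies the cohort ±1 SD
expansion/contraction rule, and feeds `plot_orientation_distribution()`
and `plot_jacobian_distribution()`.

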