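---
title: "Methods: directional analysis of white-matter lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional analysis of white-matter lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesiondir)
```

## The question and the model

Multiple sclerosis lesions are not isotropic blobs. They nucleate around
small parenchymal veins, they sit inside coherent white-matter fibre
bundles, and the periventricular ones are exposed to CSF-related
"surface-in" gradients. If those anatomical factors shape where a lesion
grows, its 3D geometry should be non-random: the long axis of the lesion
— and the direction along which it expands over time — should align with
the local vein, tract, or ventricular-surface normal more often than a
randomly oriented object would.

`lesiondir` operationalizes that question in four steps.

**1. Lesion shape as an ellipsoid.** Each labelled lesion is summarized
by the second central moment matrix of its voxel centres in world
millimetres,

$$C = \frac{1}{n}\sum_i (x_i - \bar{x})(x_i - \bar{x})^\top
      \;+\; \tfrac{1}{12} A_3 A_3^\top ,$$

whose eigenvectors are the principal axes (ε₁ = major axis) and whose
eigenvalues $m_i$ are converted to full ellipsoid axis lengths by the
solid-uniform-ellipsoid identity $\lambda_i = 2\sqrt{5 m_i}$ (the
convention of the common 3D region-properties toolboxes). The second
term — the second moment of one voxel treated as a uniform cube, mapped
through the voxel-to-world linear part $A_3$ (parallel-axis theorem) —
keeps all three axis lengths strictly positive even for planar or
single-voxel lesions; it perturbs well-resolved lesions by well under
the digitization noise, and `voxel_moment = FALSE` disables it.

Shape anisotropy applies the diffusion-tensor fractional-anisotropy
functional form to the three axis lengths,

$$\mathrm{FA}(\lambda) = \sqrt{\tfrac12}\,
 \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
             (\lambda_3-\lambda_1)^2}}
      {\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}} \in [0, 1],$$

0 for a sphere, approaching 1 for a needle. FA is invariant to a uniform
rescaling, so the axis-length convention does not affect it. Whether the
formula should consume axis lengths or raw moment eigenvalues (which
differ by a square, and give different numbers) is genuinely
underdetermined in this analysis tradition; the axis-length reading is
the default and `anisotropy_on = "moments"` switches to the alternative.

**2. Per-lesion reference axes.** Three anatomical directions, plus one
construct, are estimated within each lesion:

- *Surface-in gradient* `g`: the normalized world-space gradient of the
  Euclidean distance transform from the ventricle mask. On the
  ventricular surface this is exactly the outward surface normal; unlike
  a tangent-plane fit on surface voxels it remains defined throughout
  the white matter, which is what lesions far from the ventricles need.
  The per-lesion axis is the *signed* component-wise mean over the
  lesion's voxels — legitimate only because the distance gradient has a
  consistent outward orientation. If the mean vector's norm falls below
  0.2 the directions nearly cancel (e.g. a lesion straddling a distance
  ridge) and the axis is declared undefined with a dispersion flag.
- *Tract direction* `w`: DTI primary eigenvectors carry arbitrary signs,
  so component-wise averaging is meaningless there. Instead the
  principal eigenvector of the orientation (dyadic) tensor
  $\sum_i u_i u_i^\top$ over the lesion voxels is used — the standard
  axial-statistics mean. When the tensor's top two eigenvalues agree
  within 20% no single fibre population dominates and a crossing-fibre
  flag is raised.
- *Vein axis* `v`: the principal moment axis (same machinery as the
  lesion fit) of the vein-mask voxels intersecting the lesion. At least
  3 intersecting voxels are required — fewer cannot determine a line
  above discretization noise — otherwise the lesion is excluded from all
  vein-dependent classification, mirroring how lesions whose vein cannot
  be resolved are dropped rather than guessed at.
- *Orthogonal-to-vein* `v90`: the hypothesis that perivenular fibrosis
  constrains growth *across* the vein needs a definite perpendicular
  axis. The plane orthogonal to `v` contains infinitely many; the
  default takes the projection of the lesion's ε₁ onto that plane — the
  unique in-plane direction nearest the lesion's own major axis, which
  makes "oriented across its vein" a measurable per-lesion statement.
  When ε₁ is within 1° of the vein the projection is degenerate and a
  fixed deterministic perpendicular is used, flagged. An alternative
  "plane" reading (aligned with V90 whenever the angle to the vein
  exceeds 90° − threshold) is selectable via `v90_mode`; neither
  construction is claimed to be *the* historical one, and results under
  the default should be read with its built-in consequence in mind (see
  "Geometry of the projection construction" below).

**3. The 45° taxonomy and its chance model.** All comparisons use the
axial angle $\theta = \arccos(|a\cdot b|/\|a\|\|b\|) \in [0°, 90°]$. A
lesion is attributed to every feature whose axis lies *strictly* within
45° of ε₁ — 45° is exactly halfway between parallel and perpendicular,
so every lesion is decisively "with" or "not with" each feature, and a
measure-zero tie at the threshold falls to "not aligned". Combinations
give 11 categories (G, W, V, V90, GW, GV, WV, GWV, GV90, WV90, GWV90)
plus NONE; V and V90 can never co-occur because their axes are
perpendicular and no axis is strictly within 45° of both. A 30°
threshold is available for sensitivity analyses; tightening the
threshold can only shrink alignment sets, so lesions without a dominant
orientation can only become more numerous.

Under a uniformly random orientation, the probability of landing within
45° of one fixed axis is the fractional area of two antipodal spherical
caps, $p = 1 - \cos 45° \approx 0.293$, conventionally reported as 29%.
Joint category probabilities depend on the lesion's actual inter-axis
geometry (a vein nearly parallel to the local tracts makes WV easy and
V-alone hard), so `chance_joint()` estimates them by seeded Monte-Carlo:
uniform random axes are pushed through exactly the same classification
code, giving a per-lesion null over all 12 categories that needs no
atlas.

**4. Longitudinal change.** MTR maps are computed voxelwise as
$((\mathrm{MT_{off}} - \mathrm{MT_{on}})/\mathrm{MT_{off}}) \times 100$
(percentage units); voxels with non-positive MT-off are undefined and
counted, and values outside $[-10, 100]$ pu are flagged but never
clipped. Volume change comes from the Jacobian determinant of the
baseline→follow-up mapping, $\det(I + \nabla u)$ — the determinant of
the *mapping*, not of $\nabla u$ — with the displacement gradient taken
by central differences in world coordinates (one-sided at grid edges),
the standard tensor-based-morphometry stencil. A lesion is classified
expanding (contracting) when its mean Jacobian is at least $k = 1$
cohort standard deviation above (below) the mean over *all* included
lesions pooled across patients — the literal cohort-level reading — with
ties at $k = 0$ resolved to stable.

The major axis of expansion subtracts the lesion-mean displacement first
(separating growth from bulk motion and registration drift, to which the
Jacobian is already blind) and then takes the principal eigenvector of
the magnitude-weighted orientation tensor
$\sum_i \|u_i\|\,\hat{u}_i\hat{u}_i^\top$ of the residuals; sign-free,
so opposite-moving lesion ends reinforce. If the top two eigenvalues
agree within 10% (isotropic growth) the axis is undefined. A
strain-tensor-based alternative was considered and not implemented: on
the analytic phantom deformations the two coincide, and the
displacement-based tensor is the one the available inputs determine
directly. Direction-of-change attribution then reuses the lesion
classification contract verbatim, with `v90` reconstructed from the axis
being classified. Expansion axes are only attributed for non-stable
lesions.

**Cohort statistics.** Orientation proportions are computed within each
patient first and averaged across patients unweighted, so a
high-lesion-count patient cannot dominate the cohort percentage.
Observed-vs-chance comparisons use the exact binomial test of the pooled
category count against the analytic chance probability — the minimal
faithful null against a fixed theoretical expectation — plus a
per-patient sign summary; following the exploratory character of the
analysis no multiplicity adjustment is applied (`stats::p.adjust` is a
one-liner for users who want it). The ΔMTR-by-arm table reports
unadjusted means and SDs per category and arm; covariate-adjusted
modelling is deliberately out of scope — the per-lesion table this
package emits is exactly what such models consume.

## Coordinate and sign conventions

Voxel indices are 0-based; the NIfTI affine maps them to world
millimetres (RAS), and *all* geometry — centroids, moments, gradients,
Jacobians, angles — is computed in world mm, so voxel anisotropy (e.g.
1×1×3 mm acquisitions) does not distort directions. Axis-semantics
vector fields are stored with each vector's largest-magnitude component
non-negative, collapsing the {u, −u} ambiguity of eigenvector maps
before anything is compared or averaged; the surface-in field is the one
deliberately *signed* field (outward), and displacement fields are
signed world-mm vectors on the baseline grid.

## Geometry of the projection construction

Because the default `v90` is the projection of ε₁ into the vein-normal
plane, the angles from ε₁ to `v` and to `v90` sum to exactly 90°. At the
45° threshold this means every vein-defined lesion aligns with V or with
V90 (a tie at exactly 45°/45° falls to neither): NONE is effectively
reserved for vein-undefined lesions under this construction. This is a
geometric consequence, not a bug, and it is why the phantom generator
only accepts intended categories containing V or V90 (or `EXCLUDED`,
meaning no vein) — anything else is rejected at validation time as
unrealizable. The `v90_mode = "plane"` alternative shares the property.
Analyses that need a non-trivial NONE class under the default
construction should read it as "no alignment with g, w, or v".

## The phantom generator: what it emulates, and what it does not

`phantom_spec()` / `build_phantom()` realize a synthetic "patient" whose
every analytical ground truth is known:

- a spherical (or slab) ventricle on a 96³ grid at 1 mm isotropic
  resolution by default;
- digitized ellipsoidal lesions (centre-of-voxel inclusion against the
  analytic ellipsoid — the same convention the moment fit assumes),
  placed on a 24 mm lattice so lesions, veins and deformations never
  interact; minor semi-axes 2.0–2.4 mm with major/minor ratio 2.5–3.0
  (~120 mm³, the elongated periventricular phenotype this analysis
  targets) — large enough that the digitized moment axis recovers the
  true major axis comfortably within the 5° recovery property at 1 mm;
- per-lesion true major axes drawn by rejection so that every true
  feature angle keeps a ≥ 12° margin from the 45° boundary, making
  intended categories unambiguous;
- one vein tube (radius 0.8 mm, length 18 mm) through each non-excluded
  lesion, along ε₁ for V-intents or perpendicular for V90-intents; a
  piecewise-uniform tract axis field with the per-lesion direction
  sampled inside or outside the 45° cone as the intent requires;
- an analytic deformation field per lesion: a uniform stretch of factor
  s along the lesion axis inside a 9 mm core (where the Jacobian is
  *exactly* s), tapering smoothly to zero by 11 mm, plus an optional
  global translation; defaults inject volume ratios 1.08 / 1 / 0.92 for
  expanding / stable / contracting intents, matching the ~8% 6-month
  volume change that a 1-SD cut corresponds to in the motivating cohort;
- MT image pairs constructed to satisfy the MTR identity exactly before
  optional Gaussian noise, with baseline lesion MTR 25 pu inside 30 pu
  tissue and a prescribed per-lesion ΔMTR.

`sample_cohort()` wraps this at cohort scale. Its defaults are the
package's desk-scale study conditions: 20 patients × 16 lesions, 20% of
lesions vein-undefined (hence excluded), a category mixture proportional
to the observed per-patient means of the motivating cohort (V 33,
WV 31, GV 13, GWV 11, V90 4, WV90 3, GV90 1, GWV90 1, renormalized),
13% expanding / 7% contracting, per-lesion ΔMTR ~ N(0, 0.3) pu, and
alternating placebo/active arms with an optional category-targeted arm
effect. Per-patient seeds derive from one master seed; a fixed spec
builds a bit-identical phantom.

What the phantom deliberately does *not* emulate: MRI physics (bias
fields, partial volume beyond digitization, susceptibility contrast),
registration error, anatomically realistic ventricle/vein/tract
geometry, confluent or irregular lesion shapes, and spatially correlated
noise. Passing the recovery tests therefore demonstrates that the
*algorithms* are correct and self-consistent on data satisfying their
assumptions — it does not certify performance on clinical images, where
registration noise and atlas mismatch dominate the error budget.

## Numerical choices

- **Distance transform**: an exact separable Euclidean distance
  transform (lower-envelope-of-parabolas) with per-axis world spacing,
  implemented in C++; distances are between voxel centres. Orthogonal
  voxel axes are assumed (rigid × scale affines, the practical case).
- **Distance-map smoothing**: the raw transform measures distance to
  *discrete* surface voxels, which quantizes gradient directions by
  several degrees; a 2 mm separable Gaussian on the distance map before
  differentiation restores smooth normals. Symmetric kernels leave
  planar and spherical normals unbiased; set `smooth_sigma_mm = 0` for
  the raw field.
- **Degenerate-gradient floor**: the distance gradient has unit norm
  almost everywhere; voxels where the (smoothed) gradient norm falls
  below 0.5 sit on ridges where collision fronts meet and are marked
  undefined rather than normalized into noise.
- **Finite differences**: central in the interior, one-sided at grid
  boundaries, always converted to world coordinates through
  $A_3^{-\top}$ (gradients) or $A_3^{-1}$ (Jacobians).
- **Eigen-decompositions**: base `eigen(symmetric = TRUE)` throughout;
  eigenvector signs canonicalized (largest-magnitude component
  non-negative) so repeated runs and flipped inputs give identical
  axes. A lesion whose top two axis lengths agree within 1% gets a
  major-axis-ill-defined flag: angles to a near-degenerate axis are
  noise, and downstream users can filter on the flag.
- **Monte-Carlo**: sphere-uniform axis sampling (uniform cos θ ×
  uniform azimuth), default 10⁵ samples (SE ≤ 0.15 percentage points
  near p = 0.3), seeded through `withr` so the caller's RNG state is
  untouched.
- **Ties**: exactly-at-threshold angles do not align (strict `<`); a
  mean Jacobian exactly at the cohort mean is stable for every k.

## Problem sizes

The shipped tests validate the oracles on small analytic fixtures and
the full pipeline on a 20-patient × 16-lesion noise-free cohort at 1 mm
isotropic resolution on 96³ grids — the package's chosen desk-scale
stand-in for a trial-sized cohort, small enough to build and analyze in
well under a test run and large enough that every category and dynamics
class is populated. `scripts/acceptance.R` recomputes the analytic
chance-alignment percentage with a seeded Monte-Carlo cross-check.

## Known limitations

- The pipeline consumes *pre-registered* volumes on a common grid; it
  performs no registration and does not model the shape distortion
  non-rigid registration can introduce.
- Confluent lesions are kept as single labelled objects; their ellipsoid
  summary reflects the dominant component.
- One dominant tract direction per voxel is assumed; in heavy
  crossing-fibre regions the dyadic mean is flagged but still a single
  axis.
- The orthogonal-to-vein axis is a modelling construct; both available
  constructions are principled, neither canonical.
- With only two timepoints, slowly-evolving-lesion definitions that
  need three or more are out of reach, and the ±1 SD cut is a
  cohort-relative, not absolute, criterion.
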