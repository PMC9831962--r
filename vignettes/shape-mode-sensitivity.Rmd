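---
title: "Shape-mode sensitivity analysis of L4/L5 spinal segment mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-mode sensitivity analysis of L4/L5 spinal segment mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsusens)
```

This vignette is the package's account of its methods: the models it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic phantom can and cannot
tell you about real data.

## The problem

The mechanical response of a functional spinal unit (FSU) — two vertebrae,
the intervertebral disc, and the facet joints — depends strongly on its
geometry, and geometric features of real anatomies co-vary: disc height,
nucleus size, facet clearance and vertebral proportions do not move
independently across a population. A statistical shape model (SSM) captures
exactly these co-variations: principal component analysis of a corresponded
point-set cohort yields orthogonal *shape modes*, and sampling mode weights
generates synthetic anatomies whose feature combinations are plausible for
the training population. `fsusens` implements the full workflow from
corresponded meshes to a per-mode attribution of two axial-compression
outcomes: intradiscal pressure (IDP, the peak pressure in the nucleus
pulposus) and facet contact pressure (FCP, the peak pressure at the facet
joints).

## The shape model

Each subject is a fixed ordered list of `p` surface points flattened to a
`3p` vector `(x_1..x_p, y_1..y_p, z_1..z_p)`. After similarity alignment,
PCA gives

    s  =  s_bar + sum_m w_m * phi_m,

with orthonormal modes `phi_m` and variances `lambda_m` (sample covariance
with divisor `t - 1`; the divisor is a convention and cancels out of the
retention rule, which compares eigenvalues with their own mean). Modes are
computed by thin SVD of the centred data matrix; mode signs are arbitrary in
PCA, so each mode is flipped to make its largest-magnitude coordinate
positive, which makes fits reproducible across platforms.

Retention uses the modified Kaiser rule: keep modes with
`lambda_m >= 0.7 * lambda_bar`, where `lambda_bar` is the mean over all
modes the decomposition produced. Model quality is summarised by

* **accuracy** — RMSE between each training shape and its reconstruction
  from the retained modes;
* **specificity** — mean RMSE from model-sampled synthetic shapes to their
  nearest training shape. The sampler draws each weight from
  `Normal(0, lambda_m)` truncated at ±2 SD, for consistency with the
  synthetic-cohort sampler below; an unbounded option exists
  (`sd_trunc = Inf`) because the truncation choice is a convention.
  "Nearest" is measured by the same point-wise RMSE; 500 seeded samples by
  default;
* **generalisation** — leave-one-out reconstruction RMSE, reported against
  the number of retained modes.

All three report mean ± SD across shapes, in millimetres.

## Alignment

Shapes are registered to the first sample in a single pass (an iterative
alignment to the evolving mean is available via `iterative = TRUE` but off
by default, keeping the simpler published convention). The similarity fit is
the orthogonal Procrustes/Kabsch solution; reflections are forbidden
(`det(R) = +1`) because anatomy must not mirror, and scaling equalises
centroid sizes so that size variation does not masquerade as shape
variation. The reference shape itself is left untouched; consequently the
raw eigenvalue spectrum is expressed in the reference's scale, and only the
normalised spectrum is invariant if the reference itself is rescaled. The
per-subject transforms are retained and later applied to all volumetric
nodes when the mean template is built.

## Power analysis and sampling

The sample size for the sensitivity study is the smallest `n` at which the
test of "population R² = 0" in a 30-predictor linear regression reaches 95%
power at α = 0.05 under a medium effect ρ² = 0.15. Two formulations are
implemented: the *exact random-model* test, which uses the exact
distribution of the sample squared multiple correlation with jointly normal
random predictors (Fisher's hypergeometric-series density), and the
fixed-predictor noncentral-F approximation with noncentrality `f²·n`. The
exact random-model test is the default: mode weights in this design are
themselves random draws, which is precisely the random-model setting, and
the two formulations differ by a few subjects (the fixed-model
approximation reaches the target slightly earlier).

Weight matrices are Latin hypercube samples: for each retained mode, the
`Normal(0, lambda_m)` distribution truncated at ±2 SD is divided into `n`
equal-probability strata and one point is drawn per stratum (inverse CDF of
a uniform jitter). Truncation-then-stratification is used because plain
normal stratification would exceed the stated ±2 SD bounds; a shape sampled
beyond ±2 SD of the training variation extrapolates outside the model's
support. Under the default correlation-minimisation criterion, columns are
rearranged by an Iman–Conover-style permutation — van der Waerden scores
decorrelated through the Cholesky factor of their correlation, then each
column reordered to the ranks of the decorrelated scores — which reduces
the maximum absolute pairwise correlation while preserving every column's
marginal multiset (and hence the stratification) exactly.

## Template and thin-plate-spline morphing

The volumetric template is the node-wise mean of all training volumes after
applying the surface-estimated Procrustes transforms to every node. The SSM
only generates surface points, so interior nodes are carried to each
synthetic subject by a 3-D thin-plate spline fitted on a control subset of
corresponded surface points (default 1000 at full scale; the same control
set for every subject, drawn once and seeded). The kernel is `U(r) = r`,
the true biharmonic kernel in three dimensions (the `r² log r` kernel is
the two-dimensional one); correctness is pinned by an affine-reproduction
property test — any affine deformation is reproduced exactly at all nodes,
not just controls. Regularisation defaults to 0 (exact interpolation at
controls); duplicated or coplanar control sets raise errors naming the
offending points. Morphing never touches connectivity or labels, and each
morph reports the surface RMSE against its target together with the
fraction of elements whose corner Jacobians turned non-positive — the
quantity that feeds the element-quality failure statistics downstream.
Morph targets stay in the aligned (SSM) space throughout; transforms back
to subject scale are not applied, so mechanical outcomes are computed at
the cohort's common scale.

## Mechanical evaluation

The in-package solver is deliberately a *linear-elastic proxy*: small-strain
trilinear hexahedra with full 2×2×2 Gauss quadrature, assembled per
structure label into a sparse symmetric system, 400 N applied as a uniform
pressure over the upper bony endplate (consistent nodal loads; the pressure
amplitude is set so the integrated traction equals the total force exactly)
and the bottom endplate fully fixed. Hyperelastic structures are mapped to
linear surrogates `E = 6·C10·(1 + nu)` at `nu = 0.499`; contact at the
facets is replaced by a penalty surrogate: the post-deformation closure of
the facet gap times a penalty stiffness (140 N/mm), divided by the deformed
pad contact area, maximised over the left and right sides. IDP is the
maximum hydrostatic pressure `-tr(sigma)/3` over nucleus-element quadrature
points — quadrature stresses are the primary FE quantities, and "pressure"
is taken hydrostatic rather than principal. The full nonlinear model —
Holzapfel–Gasser–Ogden annulus with alternating ±30° fibre families,
incompressible Neo-Hookean nucleus, hard frictionless facet contact — is
not solved in-package but is exported verbatim to an Abaqus INP deck by
`export_inp()`, so external verification remains possible. Reduced
integration element types are exported as such, while the in-package solver
always integrates fully to avoid hourglass stabilisation machinery.

Before any solve, meshes are screened: all eight corner Jacobian
determinants must be positive and the scaled Jacobian must stay above a
floor (default 0.05 standalone, 0.02 in the pipeline, where the morphed
meshes' sheared facet pads legitimately sit low). Failed subjects carry
`valid = FALSE` with a reason and are excluded listwise downstream; the
failure fraction is reported, mirroring the substantial element-quality
attrition any morphing-based FE cohort shows.

Units are mm, N and MPa throughout (a consistent set).

## Uncertainty quantification

Outcome means carry sampling uncertainty. `bootstrap_ci()` computes a
percentile bootstrap of the mean (1000 iterations by default, 95% level);
the percentile method is the simplest interval consistent with "dispersion
of outcomes around the mean", and for these smooth statistics bias
correction changes little. `ci_vs_sample_size()` subsamples without
replacement at each size, freshly per size and seeded, then bootstraps
within the subsample — tracing how the interval narrows as the synthetic
cohort grows (the width shrinks like `n^{-1/2}` on iid outcomes, which is a
property test).

## Sensitivity analysis

Per mode and outcome, Pearson's linear and Spearman's rank correlations are
reported with two-sided p-values from the t-transform (`df = n - 2`;
Spearman on average ranks, which is the tie-corrected estimator).
Correlations of constant columns are reported as undefined rather than
zero. P-values are unadjusted at the 0.05 level; a Benjamini–Hochberg
adjustment can be applied by the user to the returned tibble, but the
default mirrors the single-test convention of the underlying design.

Global attribution uses kernel SHAP on an ordinary least-squares surrogate —
justified when Pearson and Spearman agree, indicating near-linear
input–output relationships (itself a property test on the phantom).
Coalitions are weighted by the Shapley kernel
`(M-1)/(C(M,s)·s·(M-s))` and enumerated in descending kernel weight, i.e.
the most extreme cardinalities first, up to the coalition budget (default
1024); a partially covered cardinality is sampled uniformly, seeded. Absent
features are replaced by the background vector — the cohort mean weight,
which is the zero vector in SD units; SHAP values are computed on SD-unit
weights (scale-free) and this is recorded in the report metadata. The
local-accuracy constraint `sum(phi) = f(x) - f(background)` is imposed
exactly via a bordered (Lagrange) system. With the exhaustive coalition set
the estimates coincide with the direct Shapley enumeration, and for a
linear surrogate with the closed form `phi_j = beta_j (x_j - bg_j)`; both
are pinned by tests at `M = 5` and `M = 6`.

Contribution percentages are normalised mean absolute Shapley values (per
outcome, summing to 100%). The "important" set is cut at the largest
consecutive relative drop among the leading ranks (window 8): the smallest
ratio `c_(i+1)/c_(i)` below 0.8 marks the cut, ties resolve toward the
smaller set, and a profile with no ratio below 0.8 (e.g. uniform
contributions) yields an empty set flagged `no_drop`.

## The phantom: what it emulates, and what it does not

The phantom generator exists so that every stage above can be tested
against known ground truth without any non-public imaging data. It
emulates the *statistical structure* of a corresponded FSU training set:

* one node ordering and one hexahedral connectivity across all subjects
  (correspondence by construction);
* all structure labels of the real segmentation — cancellous core,
  two-element cortical shell, upper/lower cartilaginous endplates, nucleus
  with exactly seven concentric annulus layers, left/right facet cartilage
  pads separated by a 0.6 mm gap;
* surface points on all exterior surfaces *and* on internal anatomical
  interfaces (the CEP–disc cross-sections and the annulus–nucleus
  boundary), as in the real protocol — interior mesh nodes carry no
  anatomical information and are excluded;
* a low-dimensional latent shape space of smooth global deformation fields:
  (1) a dominant squash-and-widen mode, (2) a nucleus-annulus ratio mode,
  (3) a facet gap/area mode, (4) a lateral shear with exactly zero effect
  on the analytic responses, plus optional taper and torsion modes. Fields
  are linear-in-position patterns with broad carriers (no concentrated
  displacement spikes), projected orthogonal to the similarity-transform
  tangent space — so Procrustes alignment cannot absorb injected variance —
  then Gram–Schmidt-orthogonalised and normalised to 1 mm RMS surface
  displacement per unit weight;
* per-subject iid isotropic Gaussian point noise (the simplest
  exchangeable noise, matching PCA's implicit normality assumption) and a
  multiplicative isotropic size factor applied *before* alignment so the
  Procrustes scaling step has something to remove.

Default study conditions: latent SDs (2.2, 0.8, 0.6, 0.45) mm, noise
0.15 mm, size spread 5%, cross-section subdivision `nc = 18` (1997 surface
points at test scale). The SD spectrum was chosen once so that the modified
Kaiser rule retains the three structured modes at `t = 30` and so that ±2 SD
samples remain valid hexahedral meshes; the shear mode's variance falls
below the retention threshold, which is realistic Kaiser-truncation
behaviour and costs nothing because its response effect is zero.

The analytic ground-truth responses are smooth functions of interpretable
geometric features measured on the surface points: nucleus width (mean
radius of the annulus–nucleus interface), disc height, facet gap and pad
area, each as a deviation from the mean phantom, with fixed coefficients.
Signs follow the physical expectations: a wider nucleus and a taller disc
lower IDP; a closing facet gap and a smaller pad area raise FCP. One
consequence of keeping the deformation fields mesh-safe is that the
dominant mode's *net* IDP effect is height-driven and positive — the
dedicated nucleus mode carries the negative nucleus–IDP correlation — so
the phantom reproduces feature-level signs, not any particular cohort's
mode-level correlation pattern. The per-mode response coefficients are
derived by central differences along each generative field and stored in
the ground truth, together with the implied importance ranking
(|coefficient| × latent SD), which the end-to-end test must recover.

What the phantom does **not** emulate: real vertebral anatomy (posterior
elements, pedicles, curvature), realistic cortical thickness variation,
non-normal shape distributions, postural variability, spatially varying or
inter-subject material properties, and contact nonlinearity. Passing tests
on the phantom therefore demonstrates the *pipeline's* correctness —
alignment, eigenstructure, sampling, morphing, solving and attribution
machinery — not the anatomical fidelity of any conclusion about real
spines.

## Numerical choices and degenerate inputs

* Procrustes: collinear point sets (rotation not identifiable) and
  mismatched point counts are errors; the scale estimate is the ratio of
  centroid sizes.
* SSM: cohorts need `t >= 3`; leave-one-out evaluation refuses
  `M > t - 2`; projection uses all available modes, reconstruction is
  capped at the retained count.
* TPS: exact interpolation at zero regularisation is asserted to 1e-8 mm;
  the bordered system is solved densely, so control counts in the low
  thousands are the practical ceiling.
* FE: the assembled stiffness is symmetrised to machine precision;
  equilibrium (reactions vs applied force) holds to 1e-8 relative because
  the solve is direct; a uniaxial patch test on a homogeneous block matches
  `sigma = -P`, `delta = PL/E` to 1e-6 relative.
* Kernel SHAP: `n_coalitions < M + 2` is refused as underdetermined;
  `M = 1` bypasses the WLS and returns `f(x) - f(background)` exactly.
* Bootstrap: constant samples give exactly zero-width intervals.

## Problem sizes

The test suite and the acceptance script run the phantom at `nc = 18`
(≈ 4000 nodes, ≈ 3250 elements, 1997 surface points), cohorts of 10–30
training subjects and 36–60 synthetic subjects, 200–300 TPS controls, and
coalition budgets of 16–64 — sizes chosen so the whole pipeline exercises
every code path in minutes on a single core. The `"paper"`-scale
configuration (152 training subjects, 500 synthetic subjects, 1000
controls, 1024 coalitions) runs the identical code and is provided for
completeness; it is slow in pure R and not exercised by the tests. The
power analysis is scale-free and always runs at the published design
settings (30 predictors, ρ² = 0.15, α = 0.05, power 0.95).

## Known limitations

* The linear-elastic proxy with near-incompressible linear surrogates
  exhibits volumetric stiffening (no selective reduced integration), so
  absolute IDP/FCP magnitudes are proxy-specific; sensitivity *rankings*
  are the meaningful output, and the INP export is the path to
  solver-grade absolute values.
* FCP from the penalty surrogate inherits the mesh- and
  definition-sensitivity that any peak contact pressure has.
* Single load case (pure axial compression), no ligaments, homogeneous
  per-structure materials.
* The SSM is linear PCA; strongly non-normal shape distributions would
  call for nonlinear shape models outside this package's scope.
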