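# fsusens

Quantifying how naturally co-varying shape features of the L4/L5 functional
spinal unit (FSU) influence its mechanical response, entirely in silico.

Spinal finite-element studies often vary discrete geometric parameters
(disc height, facet gap, ...) independently, producing anatomy combinations
that never occur in real cohorts. `fsusens` instead parameterises geometry
with a PCA statistical shape model (SSM) trained on a corresponded cohort,
samples plausible synthetic subjects from that model, evaluates a mechanical
response per subject, and attributes the outcome variation back to the shape
modes. The package is aimed at biomechanics researchers building virtual
populations and at methodologists who need a fully testable, self-contained
version of this workflow: a synthetic two-vertebra phantom cohort generator
with known ground truth stands in for non-public imaging cohorts, so every
stage can be verified against analytic oracles.

## The pipeline

1. **Phantom cohort** (`phantom_spec()`, `generate_cohort()`): `t` corresponded
   subjects, each a labelled hexahedral mesh (cancellous/cortical bone, a
   nucleus surrounded by exactly seven concentric annulus layers,
   cartilaginous endplates, facet cartilage pads), generated as
   mean phantom + Σₖ wₖ·fieldₖ + noise with known latent weights wₖ and known
   analytic IDP/FCP-like responses.
2. **Alignment** (`procrustes_fit()`, `align_cohort()`): least-squares
   similarity registration (rotation, translation, scale) of all subjects to
   the first sample; transforms are kept for re-use on full volumes.
3. **Shape model** (`ssm_fit()`): each shape is represented as
   s = s̄ + Σₘ wₘ φₘ, with modes φₘ and variances λₘ from the thin SVD of the
   centred shape matrix. Compactness is C(M) = Σ_{m≤M} λₘ / λ_total; modes are
   retained by the modified Kaiser rule λₘ ≥ 0.7·λ̄; accuracy, specificity and
   generalisation are RMSE-based (`ssm_evaluate()`).
4. **Power + sampling** (`min_sample_size()`, `latin_hypercube()`): the
   sensitivity study's sample size comes from the exact random-model test of
   the squared multiple correlation; synthetic mode-weight matrices are Latin
   hypercube samples of the per-mode truncated normal (±2 SD), rearranged by
   an Iman–Conover-style permutation to minimise pairwise correlations.
5. **Morphing** (`build_template()`, `tps_fit()`, `morph_cohort()`): the mean
   volumetric template is morphed to each synthetic surface with 3-D
   thin-plate splines (biharmonic kernel U(r) = r) driven by a fixed random
   subset of surface control points.
6. **Mechanics** (`screen_quality()`, `solve_axial()`, `batch_simulate()`):
   element-quality screening (corner/scaled Jacobians), then a linear-elastic
   trilinear-hexahedron solve under 400 N axial compression with the bottom
   endplate fixed. IDP proxy = max hydrostatic pressure −tr(σ)/3 over nucleus
   Gauss points; FCP proxy = penalty facet gap-closure force over pad area.
   `export_inp()` writes the complete Abaqus model (Holzapfel–Gasser–Ogden
   annulus, Neo-Hookean nucleus, ±30° fibres, hard frictionless facet
   contact) for external solution.
7. **Uncertainty** (`bootstrap_ci()`, `ci_vs_sample_size()`): percentile
   bootstrap (1000 iterations) of outcome means over increasing sample sizes.
8. **Sensitivity** (`correlation_map()`, `kernel_shap()`,
   `sensitivity_report()`): Pearson/Spearman significance maps and kernel
   SHAP on a linear surrogate; normalised mean |Shapley| values give each
   mode's contribution percentage, with a drop-based importance cutoff.

Results are tibbles with `tidy()`/`glance()`/`autoplot()` methods throughout.

## Worked example

```r
library(fsusens)

cfg <- pipeline_config("test", seed = 1)   # 30 phantoms, 60 synthetic subjects
res <- run_pipeline(cfg, "artifacts")

res[["power"]]
#> [1] 229

res[["train-ssm"]]
#> <fsu_ssm> 30 training shapes, p = 1997 points, 29 modes (3 retained)
#>   compactness at retained modes: 96.6%

res[["evaluate-ssm"]]
#> <ssm_performance> at M = 3 modes
#>   accuracy:        0.456 +/- 0.190 mm
#>   specificity:     0.877 +/- 0.296 mm
#>   generalisation:  0.544 +/- 0.228 mm

res[["sensitivity"]]
#> <sensitivity_report> 58/60 valid subjects
#>   outcome   mode contribution_pct rank
#> 1     fcp mode_1        60.588649    1
#> 2     fcp mode_2        25.597744    2
#> 3     fcp mode_3        13.813607    3
#> 4     idp mode_1        81.467155    1
#> 5     idp mode_3        12.616204    2
#> 6     idp mode_2         5.916641    3
#>   important (idp): mode_1
#>   important (fcp): mode_1
```

Reading this output: the design sample size for 30 predictors at ρ² = 0.15,
α = 0.05 and 95% power is 229 subjects. The SSM retains 3 modes covering
96.6% of shape variance, regenerates its training shapes to 0.46 mm RMSE and
generalises to unseen phantoms at 0.54 mm. Of the 60 synthetic subjects, 58
passed element-quality screening and were solved; the first shape mode — the
phantom's dominant injected mode (overall squash with disc widening) —
contributes 81% of the IDP variation and 61% of the FCP variation, and is
the only mode above the importance cutoff for both outcomes, matching the
generator's ground truth.

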