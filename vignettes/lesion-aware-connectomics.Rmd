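---
title: "Lesion-aware connectomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware connectomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lesionconn` analyzes resting-state functional connectivity (FC) in cohorts
with focal brain lesions. This vignette describes the statistical model
behind each stage, the parameters a user can reasonably touch, the
assumptions the synthetic-data generator does and does not emulate, and the
design decisions that were genuinely open.

## The measurement model

The input per subject and timepoint is a preprocessed 4D BOLD volume, an
integer atlas parcellation on the same voxel grid (canonically 246 regions
with a left/right lookup table), and, for patients, binary tumor and
resection masks. The package performs **no** realignment, normalization,
denoising or resampling — those belong to a preprocessing pipeline — and it
refuses mismatched grids rather than resampling silently
(`check_grid_compatibility()`, voxel-size tolerance 10⁻³ mm).

### Lesion handling

Tumor and resection masks are combined by voxelwise union
(`combine_lesion_masks()`). The combined mask serves two purposes:

1. **Voxel masking** (`apply_lesion_mask()`): lesioned voxels are set to a
   sentinel (`NA`) at every frame, so they can never contribute to a
   regional mean.
2. **ROI exclusion** (`lesioned_roi_ids()`): any atlas region intersecting
   the combined mask in at least `min_overlap_voxels` voxels (default 1,
   the strictest reading of "covers lesioned tissue") is removed from the
   node set.

Both operations use the *combined* mask at *both* timepoints. This is the
package's central contract: pre- and postoperative FC are computed over an
identical extralesional node set, so longitudinal differences cannot be
artifacts of a changing brain-volume definition. Whether exclusion should
instead use the timepoint-specific mask is not settled in the field; the
threshold and the mask choice are therefore explicit parameters, with the
combined-mask behavior as the default the pipeline enforces.

The tumor node's time course is extracted from the **unmasked**
preoperative BOLD — masking first would delete the very signal the
tumor-coupling statistic is about — and only at the preoperative timepoint,
since the tumor no longer exists after resection.

### Connectivity statistics

Regional mean series (arithmetic mean over non-sentinel voxels per frame)
are cross-correlated pairwise (Pearson over frames) and Fisher
z-transformed, `z = atanh(r)`. Correlations are clipped to
`|r| ≤ 1 − 10⁻⁷` first, so degenerate pairs yield `z ≈ 8.38` instead of
infinity. Three scalar summaries are taken from the matrix:

- **Tu-EL**: mean of the tumor row over all retained atlas nodes.
- **EL**: mean over all unordered pairs of retained atlas nodes (upper
  triangle; tumor row excluded). The alternative reading — mean of per-node
  row means — differs from the pair mean only through node-degree
  imbalance, which cannot arise here because the exclusion set is shared;
  the pair mean is the single natural scalar of the matrix and is what
  `summary_el()` computes (a test asserts it averages exactly `N(N−1)/2`
  entries).
- **conEL**: the pair mean restricted to nodes in the hemisphere opposite
  the lesion. Cross-hemispheric pairs are deliberately excluded so that the
  statistic mirrors the controls' baseline, which is necessarily
  within-hemisphere: controls have no lesion side, so their `con_el` column
  carries `control_hemispheric_baseline()`, the mean of the within-left and
  within-right pair means.

Negative z values enter all means as-is; there is no thresholding or
absolute value, so anticorrelation genuinely lowers a summary.

Nodes whose series variance falls below 10⁻¹² (or that lose all voxels to
the mask without being excluded upstream) are dropped with a warning rather
than producing undefined correlations.

An optional high-pass filter (`highpass_filter()`, default cutoff 0.01 Hz)
is provided for inputs that were not already filtered: a zero-phase
(forward–backward) order-2 Butterworth, which removes slow scanner drift
essentially completely while leaving fluctuations above the cutoff
untouched. Zero-phase filtering was chosen over a single IIR pass because
correlation statistics are phase-sensitive.

## The statistical battery

- **Outlier handling** (`winsorize_group()`): values beyond
  `mean ± 1.5·SD` are replaced by the boundary. Bounds use the *sample* SD
  (n−1) and are computed **once** from the original data — no iteration —
  and the rule is applied per group, per variable, per timepoint. Worked
  example: `[0, 1, 2, 3, 10]` has mean 3.2 and sample SD 3.962, so 10 is
  replaced by 9.143.
- **Partial correlation** (`partial_correlation()`): `x` and `y` are
  residualized on `[1, covariates]` by least squares; `r` is the Pearson
  correlation of the residuals; `t = r·√(df/(1−r²))` with `df = n − 2 − k`,
  two-sided p. With `k = 0` this is the plain Pearson test. Patients are
  adjusted for age and tumor volume, controls for age only.
- **Bonferroni** (`bonferroni_alpha()`, `adjust_p()`): `α/m` and
  `min(1, p·m)`. The family size `m` is a configuration input, never
  inferred: which tests make up a family is a scientific decision.
- **Mixed RM-ANCOVA** (`rm_ancova()`): 2 groups × 2 timepoints with
  between-subject covariates. The between-group effect is tested on subject
  means, the within effects (time, group×time) on timepoint differences,
  each in a least-squares model containing the centered covariates and an
  effect-coded group term; effects are full-vs-reduced sums-of-squares
  comparisons (Type-III-like, so results do not depend on group imbalance
  conventions). Both error terms carry `n − 2 − k` degrees of freedom,
  matching the classical mixed-design layout. With no covariate the F
  statistics coincide with the textbook two-way mixed ANOVA, which the test
  suite verifies against a brute-force sums-of-squares oracle to 10⁻⁸.
- **Multivariate group test** (`multivariate_group_test()`): Wilks' lambda
  from full-vs-reduced residual cross-products after covariate adjustment,
  converted to the exact F of the two-group case:
  `F = ((1−Λ)/Λ)·(df_den/df_num)` with `df_num = p` measures and
  `df_den = n − k − p − 1` (so 24 subjects, 5 measures and one covariate
  give F(5, 17)). The test suite cross-checks against `stats::manova`.

Listwise deletion is used throughout: a subject missing any variable an
analysis needs is dropped from that analysis (and counted in the fitted
object), never imputed.

## What the synthetic generator emulates

`synthetic_config()` fixes the study conditions; everything downstream is
deterministic given `seed`.

| Parameter | Default | Meaning |
|---|---|---|
| `n_frames`, `tr_s` | 300, 2.2 s | length and spacing of a BOLD run |
| `n_rois` | 246 | atlas size (even; half per hemisphere) |
| `base_within_corr` | 0.3 | expected pairwise r among parcels |
| `rho_tumor_range` | U(0.2, 0.8) | per-patient tumor coupling weight |
| `n_lesioned_rois` | 12 | parcels the tumor overlaps |
| `voxel_noise_sd` | 0.5 | i.i.d. voxel noise on top of parcel signals |
| `alertness_intercept`, `behavior_slope`, `behavior_noise_sd`, `age_coef` | 400, 300, 20, 1 | alertness quotient model |
| `n_patients`, `n_controls` | 18, 18 | group sizes |

Parcel signals share one common latent factor:
`s_i = √b·g + √(1−b)·ε_i`, giving expected pairwise correlation `b`
(`base_within_corr`). The tumor series is
`ρ·g + √(1−ρ²)·ε_T`, so its expected correlation with every parcel is
`ρ√b` and the expected Tu-EL value is `atanh(ρ√b)`
(`expected_tu_el()`); recovery tests compare pipeline estimates against
this closed form. A single latent factor (equicorrelation) is the simplest
structure that reproduces the *scalar mean-FC* statistics the pipeline
computes; it makes no attempt at realistic network topology.

Behavior: the alertness quotient (reaction time / correct responses,
higher = worse) is `400 + 300·z_true + 1·age + N(0, 20)`. With the default
ρ range the true coupling z spans roughly 0.1–0.5, so the planted signal
(SD ≈ 30) dominates the noise (SD 20) and the cohort-level adjusted partial
correlation is strong — around 0.8 in 18-patient replicates — comparable in
magnitude to reported tumor-coupling/attention associations in small glioma
cohorts. The four remaining scores carry a fixed patient deficit with the
conventional polarity per measure (`cognitive_measures()`) and no coupling
dependence. Age enters both behavior and the adjustment set, exercising the
covariate machinery.

`render_cohort()` writes the same model through files: a grid partitioned
into contiguous parcels (hemispheres split along x), voxel values equal to
their parcel's series plus i.i.d. noise, a contiguous tumor occupying the
planted parcels, a resection mask obtained by 6-neighborhood dilation, and
followup BOLD with the same extralesional structure but no tumor signal.
The default 8 mm voxel keeps synthetic tumor volumes in the
tens-of-cm³ range typical of gliomas while keeping file sizes small.

**What it does not emulate:** hemodynamic response shape, temporal
autocorrelation (noise is white by default, which makes correlation
standard errors *smaller* than in real BOLD — recovery tolerances are set
under this default), motion and physiological artifacts, spatial smoothing,
partial-volume effects, and any realistic anatomy. Passing recovery tests
therefore demonstrates the *estimators and their calibration*, not
performance on real scanner data.

## Numerical choices and degenerate inputs

- Correlation clip `1 − 10⁻⁷`; diagonal of the z matrix is `NA` and never
  enters a summary.
- Zero-variance winsorization input returns unchanged with a warning
  (bounds are undefined).
- `partial_correlation()` refuses rank-deficient covariates and variables
  whose residual variance is below 10⁻¹² of their total variance; `|r| = 1`
  reports the smallest positive double rather than p = 0.
- All validation (cohort invariants, grid equality, mask sides, label/LUT
  consistency) fails loudly with the offending subject and quantity named;
  the pipeline aborts naming subject and stage.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data.
Matrix-dimension and node-set contracts use the full 246-region atlas on a
14×12×6 grid with 30 frames (dimensions do not depend on T). Statistical
calibration and recovery use 40-parcel cohorts of 18 + 18 subjects at the
full T = 300: the p-value and sign-recovery properties under study are
properties of the summary statistics and do not depend on parcel count, and
40 parcels keeps hundreds of replicate cohorts comfortably cheap. Null
calibration uses 200 cohorts (Kolmogorov–Smirnov on partial-correlation
p-values) and 5000 RM-ANCOVA replicates; recovery uses 200 cohorts plus
200 subject-level draws at each ρ ∈ {0.3, 0.5, 0.8}.

## Known limitations

- Only two timepoints and two groups are supported in `rm_ancova()`; the
  multivariate test covers the two-group case (exact F) only.
- EL/conEL are global means; network-specific or graph-theoretic measures
  are out of scope.
- No partial-volume weighting or probabilistic atlases: a voxel belongs to
  exactly one parcel.
- The Bonferroni family sizes behind published adjusted thresholds are
  study-specific; the package exposes them (`m_patients`, `m_controls`) and
  defaults to the number of tests actually run.
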