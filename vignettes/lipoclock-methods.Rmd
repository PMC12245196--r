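---
title: "Methods: lipidomic aging clocks, age acceleration and lipid entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidomic aging clocks, age acceleration and lipid entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoclock)
```

## Overview

`lipoclock` implements a first-generation aging clock for brain lipidomics
and the statistics around it: preprocessing of a samples × lipids
concentration matrix, an elastic-net age predictor trained by stratified
bootstrap with out-of-bootstrap model selection, residual age acceleration,
and a reference-anchored entropy statistic. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not establish.

## Data model and preprocessing

The universal container is a `lipidomics_dataset`: a concentration matrix
(missing values allowed), a sample table (reported and standardized age,
sex, ethnicity, post-mortem interval, diagnosis ∈ {WND, ASD, SZ, DS}) and a
lipid table (name, formula, LIPID MAPS ID, molecular weight, retention
time, dolichol flag).

*Age standardization.* Reported ages include gestation; `standardize_age()`
subtracts 0.767 years so 0 is birth. Analyses run on standardized age, and
the default window is 20–80 years **inclusive at both ends** — the source
analyses state the window without endpoint handling, so we chose closed
bounds for determinism.

*Degenerate annotations.* Platforms report multiple features per LIPID MAPS
ID or chemical formula. The published screening ("conformity index") is not
formally defined anywhere we could follow, so
`resolve_duplicate_annotations()` reconstructs it as mass-conformity
selection: among contested features, keep the one whose formula-derived
monoisotopic mass (computed from a bundled atomic-mass table; no live
database queries) deviates least, in relative terms, from the annotated
molecular weight. Features lacking a molecular weight lose contested ties
(with a warning); remaining ties break lexicographically by name. This is a
defensible reconstruction, flagged as such in the function's messages.

*Outlier screening.* `detect_outliers()` mean-fills missing cells (for this
step only), projects samples onto the leading principal components of the
covariance matrix (components kept to 95% cumulative variance by default)
and averages each sample's pairwise Euclidean distances in that space. The
published rule brackets the mean distances by "first/third percentile
± 3 × the interquartile range", which admits two readings; the default
anchors the bounds at the 1st/99th *percentiles* while taking the IQR from
the true quartiles (honouring both the percentile wording and the
interquartile range), and `bounds = "quartile"` gives the plain Tukey-style
Q1/Q3 version. Covariance (not correlation) PCA is used here so the screen
is exactly invariant under rigid rotations of the data; the clock's PCA
(below) is correlation-based.

*Imputation and normalization.* `fit_transform()` learns, on training data
only: K-nearest-neighbour imputation (k = 5; distances on mutually observed
lipids, rescaled by the observed fraction; a cell is imputed as the mean of
the k nearest donors that observe that lipid, and observed values are never
altered), then a per-lipid Yeo-Johnson transform with λ estimated by
profile maximum likelihood (search interval [−5, 5], `optimize()` tolerance
1e-6; λ = 1 is returned for degenerate or near-constant input and is an
exact identity, and also when an extreme λ would numerically collapse the
transformed column — saturation near the interval boundary can shrink the
column's spread below float precision, which would make the subsequent
scaling ill-conditioned), then centering/scaling to mean 0, sd 1 on the
training samples. `apply_transform()` imputes test cells from *training* donors
only, so a sample's transform never depends on which other samples
accompany it — the property that makes out-of-bootstrap evaluation honest.

## The clock

`lipid_clock()` regresses standardized age on features plus covariates with
an elastic net: objective `(1/2n)·RSS + λ(α‖β‖₁ + (1−α)/2·‖β‖₂²)`,
intercept unpenalized, defaults λ = 1 and α = 0.5 — the conventional
defaults of the reference implementations. Feature modes:

- `dolichols_only`: the dolichol-flagged lipids after the transform;
- `pca_all_lipids`: scores on the leading eigenvectors of the full panel's
  correlation matrix `S = QΛQᵀ` (eigenvalues sum to the number of retained
  features; eigenvector signs fixed so the largest-magnitude loading is
  positive). The number of components defaults to 95% cumulative variance
  and is configurable (`n_pcs`).

Covariates (sex, ethnicity, post-mortem interval in hours) enter as
penalized features by default — the source states that covariates were
"incorporated" without saying whether they were penalized; we chose the
penalized reading because it matches fitting a single elastic net on the
concatenated design, and expose `unpenalized_covariates = TRUE`
(per-column zero penalty factors) for the adjustment reading. Sex and
ethnicity are one-hot encoded with the first level dropped; prediction on
an unseen level is an error rather than a silent zero. The post-mortem
interval is centred/scaled with training statistics.

*Bootstrap.* `run_bootstrap()` trains on healthy (WND) samples only,
resampling with replacement within strata (5-year age bin × sex ×
ethnicity) so each iteration preserves the original size and demographic
composition. The transform and any PCA basis are refit inside every
iteration on that iteration's resample. Each model is scored by the median
absolute error on its out-of-bootstrap samples; iterations with an empty
out-of-bootstrap set are recorded as missing and excluded from selection
(possible under fine strata — a stratum of size 1 is always redrawn).
`select_median_model()` returns the model attaining the sample median of
the valid errors, taking the lower-middle element for even counts and the
earliest iteration on ties — determinism over elegance. The reference
procedure uses 10,000 iterations (the `pipeline_config()` default); the
package's validation suite runs 200 and additionally checks that the
selected model's error lies within the interquartile range of all
iterations, which is the property that makes the scaled-down count safe.

*Age acceleration.* `compute_age_acceleration()` fits ordinary least
squares of predicted on chronological age **on the healthy group only** —
fitting on all samples would let the disorder offsets contaminate the
reference line — and takes every sample's residual from that line. Groups
are compared with two-sided Mann-Whitney U tests against the healthy
residuals, Holm-Bonferroni adjusted across groups.

## Entropy

`fit_reference()` anchors the statistic to healthy samples aged 20–40 (the
assumed window of stable prefrontal-cortex lipid regulation): a per-lipid
Yeo-Johnson transform and the post-transform mean/sd are estimated on that
window only. `binarize()` marks a value deviant when it falls **strictly**
more than `threshold` (default 2) reference SDs from the reference mean;
a value at exactly 2 SD is not a deviation, and missing cells count as no
deviation (their number is reported).

Group entropy (`group_entropy()`): within 10-year age bins, each lipid's
deviation proportion `f` gives the binary entropy
`h = −f log₂ f − (1−f) log₂(1−f)` (so `h ≤ 1` bit, with `0·log 0 ≡ 0`), and
the bin's summary is the **mean** over lipids — mean rather than sum so
panels of different size are comparable. Base-2 logarithms are used
throughout (the source does not state a base; bits are the natural unit for
binary deviations).

Individual entropy (`individual_entropy()`): the published recipe — weight
deviations by their rarity among age-matched healthy people, then "compute
entropy" — is ambiguous, so two readings are implemented and neither is
privileged as ground truth. The default (`mode = "weighted"`) converts the
surprisals `w_j = −log₂ f_j` of a sample's deviating lipids into a
distribution `q = w/Σw` and reports its Shannon entropy (0 for no or a
single deviation, at most `log₂` of the deviation count);
`mode = "surprisal-sum"` reports `Σ w_j` instead. Reference frequencies are
clipped to `[ε, 1−ε]` with `ε = 1/(2·n_bin)` — the standard continuity
correction that keeps weights finite when a deviation was never seen in the
reference. `entropy_contributors()` reports each sample's largest-surprisal
deviating lipid (lexicographic tie-break), and `dolichol_entropy()` runs
the same machinery on the dolichol submatrix.

When comparing entropy between age bins, the per-**sample** entropy values
are the test unit (Mann-Whitney between bins, Holm-adjusted), matching the
boxplot-by-age-bin analysis; the per-lipid, per-bin entropies are also
exposed for panel-level views.

## Supporting statistics and interpretation

`mann_whitney_u()` (exact enumeration for small tie-free samples,
tie-corrected normal approximation otherwise), `holm_bonferroni()`,
`levene_test()` (classical mean-centred Levene via one-way ANOVA on
absolute deviations; `center = "median"` gives Brown-Forsythe),
`slope_comparison()` (OLS with group × age interactions; reduces to simple
OLS when only the reference group is present), `pearson_r()` /
`correlation_matrix()` (pairwise-complete; zero-variance features give NA
with a warning) and `log_fold_change()` (log₂ of the ratio of raw-scale
group means; non-positive means give NA with a warning). Two-sided tests
are the default throughout. Hypothesis-driven families use Holm; wide
exploratory scans should use plain Bonferroni at the actual comparison
count rather than a hard-coded threshold.

Because the clock is linear in its features, Shapley attributions under an
interventional background expectation have an exact closed form:
`linear_shap()` computes `φ_j(x) = β_j (x_j − mean_bg(x_j))` with base
value `intercept + β·mean_bg` (background = training set by default), so
the efficiency identity `base + Σφ = prediction` is exact — asserted to
1e-10 in the tests, no sampling approximation involved. `pc_importance()`
maps PC-space coefficients back to lipids as `Q β`. `mi_rescale()` scales
eigenvectors by the estimated mutual information between their scores and a
target; the published mutual-information construction could not be
reconstructed from its description, so a histogram estimator on
equal-frequency bins (10 by default) stands in with the same contract:
non-negative, approximately zero under independence, invariant to strictly
monotone transforms of the score. Its small-sample positive bias is why the
independence check in the tests compares against a permutation null rather
than zero.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with ground truth retained for recovery tests:

- chronological ages uniform on 20–80; biological age = chronological age
  + the diagnosis group's offset + Gaussian jitter (sd 2 y by default);
- dolichols: linear in biological age (slope 0.5 concentration units/year)
  with heteroscedastic noise `sd(age) = sd₀·(1 + 0.5·(age−20)/10)` —
  linear-in-decades variance growth, the minimal structure matching the
  qualitative several-fold spread increase seen in aged cohorts;
- non-dolichols: a mix of flat and weakly age-related lipids (slopes
  uniform in ±0.05 units/year), a subset carrying an additive
  ethnicity-linked mean shift;
- missingness completely at random at 1.98%.

Cohort defaults (242 samples; 163 lipids; group composition
195 WND : 15 ASD : 27 SZ : 5 DS; offsets +6/+6/+8 years for ASD/SZ/DS)
mirror the reference cohort's composition. Effect sizes for the disorder
offsets and ethnicity shifts are not published; the defaults were chosen
once for testability (offsets detectable at the reference group sizes) and
are not tuned thereafter. `clock_noise_floor()` converts the generator
parameters into the best achievable median absolute error — jitter plus the
dolichol measurement noise mapped through the slopes — which is the
yardstick the bootstrap error is validated against.

What the generator does *not* emulate: mass spectra, m/z values, isotope
envelopes, retention-time drift, non-random missingness, correlated noise
across lipids, non-linear dolichol trajectories, or realistic effect sizes
for ethnicity and the disorders. Passing tests therefore establish that the
pipeline recovers known structure of this idealized kind — not that the
reference cohort's published effect sizes would be reproduced on real data.

## Validation problem sizes

The test-suite and acceptance-script simulations use: 20 reference cohorts
of n = 200 for binarization calibration; 50 cohorts of n = 400 for the
entropy analyses; 100 cohorts of n = 220 (150/30/30/10 per group) for
acceleration power; 200 bootstrap iterations for clock evaluation; and
2000 resampling iterations for the out-of-bootstrap fraction. These sizes
give Monte-Carlo error comfortably below the decision margins they feed.

## Known limitations

- The conformity index, the individual-entropy weighting and the
  mutual-information estimator are reconstructions of under-specified
  procedures; each is documented above and at its function.
- Elastic-net shrinkage compresses predictions toward the training mean,
  so recovered acceleration offsets are attenuated relative to the
  generating offsets (the regression line absorbs the slope part; the
  residual comparison remains valid).
- The KNN imputer is O(samples²·lipids) per call; it is comfortable at
  cohort scale (hundreds of samples) but not optimized for thousands.
- PCA-mode clocks drop zero-variance lipids with a warning; lipids absent
  from a prediction dataset are an error, not imputed.
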