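# lipoclock

Lipidomic aging clocks, residual age acceleration and lipid-entropy
statistics for post-mortem brain lipidomics.

## The problem

Dolichols — polyprenol lipids with a variable isoprene-unit count
(dolichol-19, dolichol-20, ...) that carry the glycan precursors of
N-glycosylation — accumulate in brain tissue with age. That makes them
candidate features for a *first-generation aging clock*: a model that
predicts chronological age from a molecular profile, so that systematic
over-prediction in a diagnostic group (autism spectrum disorder,
schizophrenia, Down syndrome) can be read as *age acceleration*.
`lipoclock` is for researchers who want to fit such clocks to
samples × lipids concentration matrices with demographic covariates, and to
quantify the growing heterogeneity ("entropy") of lipid profiles across the
lifespan.

## The models

**Clock.** For sample $i$ with (Yeo-Johnson normalized, scaled) lipid
features $x_i$ and covariates $c_i$ (sex, ethnicity one-hot; post-mortem
interval scaled), the clock solves the elastic net

$$\min_{\beta,\beta_0}\; \tfrac{1}{2n}\sum_i (y_i - \beta_0 - \beta^\top [x_i; c_i])^2
  + \lambda\big(\alpha\lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\big)$$

with $y_i$ the standardized chronological age (reported age minus a 0.767-y
gestational period), defaults $\lambda = 1$, $\alpha = 0.5$. Features are
either the dolichol panel (`dolichols_only`) or principal-component scores
of the full panel from the correlation-matrix eigendecomposition
$S = Q\Lambda Q^\top$ (`pca_all_lipids`). Training uses stratified
bootstrap resampling (5-year age bins × sex × ethnicity, original sample
size preserved, healthy samples only); each iteration refits the
imputation/normalization transform and is scored on its out-of-bootstrap
samples by median absolute error, and the median-performing model is kept.
Age acceleration is a sample's residual from the healthy-group regression
of predicted on chronological age; groups are compared by Mann-Whitney U
with Holm-Bonferroni correction.

**Entropy.** A reference model is fitted on healthy 20–40-year-olds; a
lipid value is a *deviation* when it falls more than 2 reference SDs from
the reference mean after normalization. Within 10-year age bins, each
lipid's deviation proportion $f$ gives a binary entropy
$h = -f\log_2 f - (1-f)\log_2(1-f)$ (group level), and each sample gets a
rarity-weighted entropy over its deviating lipids, with weights
$w_j = -\log_2 f_j$ taken from age-matched healthy references.

A synthetic cohort generator (`generate_cohort()`) reproduces the
statistical structure these methods assume — linear dolichol accumulation
with age-growing variance, additive disorder offsets on biological age,
ethnicity-shifted lipids, ~2% missingness — with full ground truth, so
every stage is testable against known answers.

## Worked example

```r
library(lipoclock)

cohort <- generate_cohort(synthetic_config(seed = 1))
cohort
#> lipidomics_dataset: 242 samples x 163 lipids
#>   missing cells: 768 (1.95%)
#>   diagnosis: ASD=15 DS=5 SZ=27 WND=195
#>   dolichols: 6

boot  <- run_bootstrap(cohort, n_iter = 200, seed = 1)
boot
#> clock_bootstrap: 200 iterations ( 0 without out-of-bootstrap samples )
#>   out-of-bootstrap MAE (years): median 2.00, IQR [1.87, 2.22]

clock <- select_median_model(boot)
summary(clock)
#> lipid_clock (dolichols_only)
#>   trained on 195 samples; 10 features (6 nonzero)
#>   penalty: mixing 0.50, strength 1
#>   training median absolute error: 1.98 years
#>   training r(predicted, age): 0.982

pred  <- predict(clock, cohort)
compute_age_acceleration(pred, cohort$samples$standardized_age,
                         cohort$samples$diagnosis)
#> acceleration_report (reference: WND )
#>   expected trajectory: predicted = 3.430 + 0.934 * age
#>   group comparisons (Mann-Whitney vs reference, Holm-adjusted):
#>  group  n n_ref statistic        p median_delta p_adjusted
#>    ASD 15   195      2637 2.26e-07         5.14   4.52e-07
#>     DS  5   195       968 1.73e-04         7.51   1.73e-04
#>     SZ 27   195      4597 3.41e-10         4.11   1.02e-09
```

The out-of-bootstrap MAE of ~2 years sits just above the cohort's
irreducible error (`clock_noise_floor()`), and the disorder groups — whose
generated biological ages carry +6/+6/+8-year offsets — are all detected
with Holm-adjusted p < 0.001; the median residuals (5.1, 7.5, 4.1 years)
estimate those offsets after regression-line compression.

The entropy side:

```r
ref <- fit_reference(cohort)              # healthy 20-40 window
hd  <- dolichol_entropy(cohort, ref)      # per-sample, dolichols only
pearson_r(hd, cohort$samples$standardized_age)$r
#> [1] 0.8544677
```

`run_pipeline(pipeline_config(...), "runs/demo")` executes the whole chain
(generation → preprocessing → bootstrap clock → entropy → statistics →
attribution) into a run directory with a deterministic manifest;
`make_report("runs/demo")` renders the artifacts as markdown.

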