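Package: lipoclock
Title: Lipidomic Aging Clocks, Age Acceleration and Lipid Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits lipid-based biological aging clocks for post-mortem brain
    lipidomics: an elastic-net age predictor trained on dolichol species
    (with sex, ethnicity and post-mortem interval as covariates) and a
    variant fitted on principal-component projections of the full lipid
    panel. Models are trained by stratified bootstrap resampling with
    out-of-bootstrap evaluation and median-model selection; residuals from
    the regression of predicted on chronological age quantify age
    acceleration in disorder groups. Also provides a reference-anchored
    Shannon-entropy statistic for lipid profiles (group-level within age
    bins and rarity-weighted per-sample entropy), preprocessing utilities
    (age standardization, K-nearest-neighbour imputation, Yeo-Johnson
    normalization, PCA-distance outlier screening, duplicate-annotation
    resolution), the supporting statistical battery (Mann-Whitney,
    Holm-Bonferroni, Levene, slope comparisons, correlations, fold
    changes), exact linear feature attribution, and a synthetic cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
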