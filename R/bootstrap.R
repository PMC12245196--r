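#' Stratified bootstrap index sets
#'
#' Resamples with replacement *within* each stratum, preserving every
#' stratum's count (and hence the original sample size) in each iteration.
#'
#' @param strata factor-like vector, one stratum label per sample; no
#'   stratum may be empty.
#' @param n_iter number of bootstrap iterations, `>= 1`.
#' @param seed integer RNG seed.
#' @return list of `n_iter` integer index vectors.
#' @export
stratified_indices <- function(strata, n_iter, seed = 1L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  strata <- factor(strata)
  if (any(table(strata) == 0)) stop("empty stratum")
  groups <- split(seq_along(strata), strata, drop = TRUE)
  local_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
    })
  })
}

# 5-year age bins x sex x ethnicity, the bootstrap stratification
.clock_strata <- function(samples, age_bin = 5) {
  interaction(floor(samples$standardized_age / age_bin),
              samples$sex, samples$ethnicity, drop = TRUE)
}

#' Run the stratified bootstrap for a lipid clock
#'
#' Trains one [lipid_clock()] per bootstrap iteration on a resample of the
#' healthy (reference-group) samples — stratified by 5-year age bin, sex
#' and ethnicity, preserving the original sample size — and scores it on
#' the out-of-bootstrap samples (those never drawn in that iteration) by
#' median absolute error.  The transform (imputation, normalization) and
#' any PCA basis are refit inside every iteration on that iteration's
#' bootstrap sample only.  Iterations whose out-of-bootstrap set is empty
#' are recorded as `NA` and excluded from model selection.
#'
#' @param dataset a [lipidomics_dataset()]; only `training_group` samples
#'   are used for training.
#' @param n_iter number of bootstrap iterations (the reference procedure
#'   uses 10,000; validation suites use a few hundred).
#' @param seed integer RNG seed.
#' @param training_group diagnosis label of the training samples.
#' @param age_bin stratification age-bin width (years).
#' @param ... passed to [lipid_clock()] (feature_mode, covariates, mixing,
#'   strength, ...).
#' @return object of class `clock_bootstrap`: per-iteration
#'   out-of-bootstrap MAEs, fitted models, strata and seed.
#' @export
run_bootstrap <- function(dataset, n_iter = 200, seed = 1L,
                          training_group = "WND", age_bin = 5, ...) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  train <- subset_dataset(dataset,
                          samples = dataset$samples$diagnosis == training_group)
  n <- nrow(train$values)
  if (n < 10) stop("too few training samples (", n, ")")
  strata <- .clock_strata(train$samples, age_bin)
  idx_sets <- stratified_indices(strata, n_iter, seed)

  maes <- rep(NA_real_, n_iter)
  oob_frac <- rep(NA_real_, n_iter)
  models <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    idx <- idx_sets[[it]]
    oob <- setdiff(seq_len(n), unique(idx))
    oob_frac[it] <- length(oob) / n
    model <- lipid_clock(subset_dataset(train, samples = idx), ...)
    models[[it]] <- model
    if (length(oob)) {
      oob_ds <- subset_dataset(train, samples = oob)
      pred <- predict(model, oob_ds)
      maes[it] <- stats::median(abs(pred - oob_ds$samples$standardized_age))
    }
  }
  if (all(is.na(maes)))
    message("run_bootstrap: no iteration had out-of-bootstrap samples")
  structure(list(mae = maes, models = models, oob_fraction = oob_frac,
                 strata = strata, seed = seed, n_iter = n_iter,
                 training_group = training_group, age_bin = age_bin),
            class = "clock_bootstrap")
}

#' @export
print.clock_bootstrap <- function(x, ...) {
  ok <- !is.na(x$mae)
  cat("clock_bootstrap:", x$n_iter, "iterations (",
      sum(!ok), "without out-of-bootstrap samples )\n")
  if (any(ok)) {
    q <- stats::quantile(x$mae[ok], c(0.25, 0.5, 0.75))
    cat(sprintf("  out-of-bootstrap MAE (years): median %.2f, IQR [%.2f, %.2f]\n",
                q[2], q[1], q[3]))
  }
  invisible(x)
}

#' Select the median-performing bootstrap model
#'
#' Returns the model whose out-of-bootstrap MAE attains the sample median
#' of all valid iterations (the lower-middle element for even counts); ties
#' resolve to the earliest iteration.  Deterministic.
#'
#' @param result a [run_bootstrap()] object.
#' @return the selected `lipid_clock`, with `oob_mae` and `iteration` set.
#' @export
select_median_model <- function(result) {
  stopifnot(inherits(result, "clock_bootstrap"))
  valid <- which(!is.na(result$mae))
  if (!length(valid)) stop("no valid bootstrap iteration")
  vals <- sort(result$mae[valid])
  target <- vals[floor((length(vals) + 1) / 2)]
  chosen <- min(valid[result$mae[valid] == target])
  model <- result$models[[chosen]]
  model$oob_mae <- result$mae[chosen]
  model$iteration <- chosen
  model
}
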