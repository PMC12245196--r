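#' Standardize reported age by removing the gestational period
#'
#' Post-mortem ages are reported from conception-inclusive records; a
#' gestational period of 0.767 years is subtracted so age 0 corresponds to
#' birth.
#'
#' @param reported_age numeric vector of reported ages (years), `>= 0`.
#' @return standardized ages: `reported_age - 0.767`.
#' @export
standardize_age <- function(reported_age) {
  if (any(reported_age < 0, na.rm = TRUE))
    stop("reported_age must be >= 0")
  reported_age - GESTATION_YEARS
}

#' Filter a dataset to a standardized-age window
#'
#' Retains samples with `lo <= standardized_age <= hi` (bounds inclusive).
#' An empty result is permitted; downstream stages raise their own errors.
#'
#' @param dataset a [lipidomics_dataset()].
#' @param lo,hi age bounds in years, `lo < hi`.
#' @return the filtered dataset.
#' @export
filter_age_range <- function(dataset, lo = 20, hi = 80) {
  if (lo >= hi) stop("lo must be < hi")
  keep <- dataset$samples$standardized_age >= lo &
    dataset$samples$standardized_age <= hi
  subset_dataset(dataset, samples = keep)
}

# monoisotopic atomic masses for the elements seen in lipid formulas;
# local stand-in for live LIPID MAPS adduct searches (out of scope)
.ATOMIC_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                  O = 15.99491461956, P = 30.97376163, S = 31.972071,
                  Na = 22.9897692809, K = 38.96370668, Cl = 34.96885268)

#' Monoisotopic mass from a chemical formula
#'
#' @param formula character vector like `"C95H160NO"`.
#' @return numeric masses (Da); `NA` for unparseable formulas.
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!length(toks) || sum(nchar(toks)) != nchar(f)) return(NA_real_)
    total <- 0
    for (t in toks) {
      el <- gsub("[0-9]", "", t)
      cnt <- gsub("[^0-9]", "", t)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.ATOMIC_MASS)) return(NA_real_)
      total <- total + .ATOMIC_MASS[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# within a group of contesting features, pick the winner: smallest relative
# deviation between formula-derived mass and annotated molecular weight;
# missing molecular weight loses ties; lexicographic name as final tie-break
.pick_best <- function(sub) {
  dev <- abs(formula_mass(sub$formula) - sub$molecular_weight) /
    sub$molecular_weight
  if (any(is.na(dev)))
    warning("feature(s) ", paste(sub$name[is.na(dev)], collapse = ", "),
            " lack a usable molecular weight and lose duplicate ties",
            call. = FALSE)
  ord <- order(is.na(dev), dev, sub$name)
  sub$name[ord[1]]
}

#' Resolve degenerate lipid annotations
#'
#' Retains at most one feature per LIPID MAPS ID and per chemical formula.
#' Among contested features the one whose formula-derived mass deviates
#' least (relative) from the annotated molecular weight is kept;
#' ties break lexicographically by feature name.  This mass-conformity
#' selection is a reconstruction of the original degeneracy screen and is
#' logged as such.
#'
#' @param dataset a [lipidomics_dataset()].
#' @return the dataset with duplicate annotations resolved.
#' @export
resolve_duplicate_annotations <- function(dataset) {
  lip <- dataset$lipids
  keep <- rep(TRUE, nrow(lip))

  resolve_by <- function(key, keep) {
    ok <- keep & !is.na(key) & nzchar(as.character(key))
    for (g in unique(key[ok])) {
      idx <- which(ok & key == g)
      if (length(idx) > 1) {
        winner <- .pick_best(lip[idx, , drop = FALSE])
        keep[idx[lip$name[idx] != winner]] <- FALSE
      }
    }
    keep
  }
  keep <- resolve_by(lip$lm_id, keep)
  keep <- resolve_by(lip$formula, keep)
  if (!all(keep))
    message("resolve_duplicate_annotations: dropped ", sum(!keep),
            " degenerate feature(s) by mass-conformity (reconstructed rule)")
  subset_dataset(dataset, lipids = keep)
}

#' Detect outlying samples by mean pairwise PCA distance
#'
#' Missing cells are mean-filled for this step only; samples are projected
#' onto the leading principal components (covariance PCA, components kept up
#' to `var_explained` cumulative variance) and the pairwise Euclidean
#' distances in that space are averaged per sample.  A sample is flagged
#' when its mean distance falls strictly outside
#' `[pct_lo - mult*IQR, pct_hi + mult*IQR]`.
#'
#' @param dataset a [lipidomics_dataset()].
#' @param n_components fixed number of components (overrides
#'   `var_explained`); truncated with a message if it exceeds the rank.
#' @param var_explained cumulative variance target for component retention.
#' @param iqr_mult multiplier of the interquartile range.
#' @param bounds `"percentile"` anchors the bounds at the 1st/99th
#'   percentiles (IQR still the true quartile spread); `"quartile"` uses
#'   Q1/Q3 as the anchors.  Linear interpolation throughout.
#' @return an object of class `outlier_report`: per-sample mean distance,
#'   bounds, and flagged sample ids.
#' @export
detect_outliers <- function(dataset, n_components = NULL,
                            var_explained = 0.95, iqr_mult = 3,
                            bounds = c("percentile", "quartile")) {
  bounds <- match.arg(bounds)
  x <- dataset$values
  if (nrow(x) < 4) stop("need at least 4 samples")
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  keep <- apply(x, 2, stats::var) > 0
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  m_avail <- sum(ev > 1e-12)
  if (!is.null(n_components)) {
    m <- n_components
    if (m > m_avail) {
      message("detect_outliers: truncating components from ", m,
              " to ", m_avail)
      m <- m_avail
    }
  } else {
    m <- which(cumsum(ev) / sum(ev) >= var_explained)[1]
  }
  scores <- pc$x[, seq_len(m), drop = FALSE]
  d <- as.matrix(stats::dist(scores))
  md <- rowSums(d) / (nrow(d) - 1)
  q <- stats::quantile(md, c(0.01, 0.25, 0.75, 0.99), type = 7, names = FALSE)
  iqr <- q[3] - q[2]
  lim <- switch(bounds,
                percentile = c(q[1] - iqr_mult * iqr, q[4] + iqr_mult * iqr),
                quartile   = c(q[2] - iqr_mult * iqr, q[3] + iqr_mult * iqr))
  flagged <- md < lim[1] | md > lim[2]
  structure(list(mean_distance = setNames(md, dataset$samples$sample_id),
                 lower = lim[1], upper = lim[2],
                 n_components = m,
                 flagged = dataset$samples$sample_id[flagged]),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report:", length(x$mean_distance), "samples,",
      x$n_components, "components\n")
  cat(sprintf("  bounds: [%.4g, %.4g]\n", x$lower, x$upper))
  cat("  flagged:", if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Fit the imputation + normalization transform on training data
#'
#' K-nearest-neighbour imputation (distance on mutually observed lipids)
#' followed by a per-lipid Yeo-Johnson transform (lambda by maximum
#' likelihood) and centering/scaling to mean 0, sd 1 on the training
#' samples.  The state is fitted once, on training data only, and projected
#' onto any later data with [apply_transform()].
#'
#' @param dataset training [lipidomics_dataset()]; needs at least `k + 1`
#'   samples and no all-missing lipid.
#' @param k number of imputation neighbours.
#' @return an object of class `transform_state`.
#' @export
fit_transform <- function(dataset, k = 5) {
  x <- dataset$values
  if (nrow(x) < k + 1) stop("need at least k + 1 training samples")
  allmiss <- colSums(!is.na(x)) == 0
  if (any(allmiss))
    stop("all-missing lipid(s) in training data: ",
         paste(colnames(x)[allmiss], collapse = ", "))
  ximp <- .knn_impute(x, x, k)
  lambda <- apply(ximp, 2, yj_lambda)
  z <- ximp
  for (j in seq_len(ncol(z))) z[, j] <- yeo_johnson(ximp[, j], lambda[j])
  center <- colMeans(z)
  scale <- apply(z, 2, stats::sd)
  zero <- scale == 0
  if (any(zero)) {
    warning("zero post-transform variance for lipid(s): ",
            paste(colnames(x)[zero], collapse = ", "), "; scale set to 1")
    scale[zero] <- 1
  }
  structure(list(k = k, lambda = lambda, center = center, scale = scale,
                 train_raw = x, lipid_names = colnames(x),
                 train_ids = rownames(x)),
            class = "transform_state")
}

#' Apply a fitted transform to a dataset
#'
#' Missing cells are imputed from the k nearest *training* samples (so the
#' result for a sample never depends on which other samples are transformed
#' with it), then the stored Yeo-Johnson and scaling parameters are applied.
#'
#' @param state a [fit_transform()] result.
#' @param dataset a [lipidomics_dataset()] covering the state's lipids.
#' @return the dataset with `values` replaced by transformed values (lipids
#'   restricted and ordered as in the state).
#' @export
apply_transform <- function(state, dataset) {
  stopifnot(inherits(state, "transform_state"))
  idx <- match(state$lipid_names, dataset$lipids$name)
  if (any(is.na(idx)))
    stop("dataset lacks lipid(s): ",
         paste(state$lipid_names[is.na(idx)], collapse = ", "))
  ds <- subset_dataset(dataset, lipids = idx)
  x <- ds$values
  ximp <- .knn_impute(x, state$train_raw, state$k)
  z <- ximp
  for (j in seq_len(ncol(z)))
    z[, j] <- (yeo_johnson(ximp[, j], state$lambda[j]) - state$center[j]) /
      state$scale[j]
  ds$values <- z
  ds
}
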