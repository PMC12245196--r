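#' Per-lipid importance from PCA loadings and model coefficients
#'
#' For a PCA-mode clock, maps the elastic-net coefficients on principal
#' components back to the original lipids: `importance = Q[, used] %*%
#' beta_pc`, one value per lipid.
#'
#' @param model a [lipid_clock()] fitted with `feature_mode =
#'   "pca_all_lipids"`.
#' @return named numeric vector, one importance per lipid.
#' @export
pc_importance <- function(model) {
  stopifnot(inherits(model, "lipid_clock"))
  if (model$feature_mode != "pca_all_lipids")
    stop("pc_importance requires a PCA-mode model")
  pcs <- paste0("PC", seq_len(model$n_pcs))
  beta_pc <- model$beta[pcs]
  imp <- as.numeric(model$pca$Q[, pcs, drop = FALSE] %*% beta_pc)
  setNames(imp, rownames(model$pca$Q))
}

#' Exact feature attribution for a linear clock
#'
#' The clock is linear in its (transformed) features, so Shapley values
#' under an interventional background expectation have the exact closed
#' form `phi_j(x) = beta_j * (x_j - mean_bg(x_j))`, with base value
#' `intercept + beta . mean_bg`.  The efficiency identity
#' `base + sum(phi) = prediction` holds exactly for every sample — no
#' sampling approximation is involved.
#'
#' @param model a [lipid_clock()].
#' @param dataset samples to attribute, a [lipidomics_dataset()].
#' @param background background [lipidomics_dataset()] defining the
#'   expectation; default: the model's training set.
#' @return object of class `attribution_table`: `phi` (samples x features,
#'   years), `base`, `prediction`, and `ranking` by mean absolute
#'   attribution.
#' @export
linear_shap <- function(model, dataset, background = NULL) {
  stopifnot(inherits(model, "lipid_clock"))
  X <- .clock_design(model, dataset)
  bg <- if (is.null(background)) model$X_train
        else .clock_design(model, background)
  if (!identical(colnames(bg), colnames(X)))
    stop("background features do not match the model design")
  mu <- colMeans(bg)
  phi <- sweep(X, 2, mu) *
    matrix(model$beta, nrow(X), ncol(X), byrow = TRUE)
  rownames(phi) <- dataset$samples$sample_id
  base <- model$intercept + sum(model$beta * mu)
  pred <- as.numeric(model$intercept + X %*% model$beta)
  rk <- sort(colMeans(abs(phi)), decreasing = TRUE)
  structure(list(phi = phi, base = base,
                 prediction = setNames(pred, dataset$samples$sample_id),
                 ranking = rk),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat("attribution_table:", nrow(x$phi), "samples x", ncol(x$phi),
      "features; base value", sprintf("%.2f", x$base), "years\n")
  cat("  top features by mean |phi|:\n")
  print(round(utils::head(x$ranking, 5), 4))
  invisible(x)
}

#' Summarize attributions by age decade
#'
#' Mean absolute attribution per feature within decade bins of
#' chronological age — the standard view of how feature influence shifts
#' across the lifespan.
#'
#' @param attr an [linear_shap()] result.
#' @param ages chronological ages, one per attributed sample.
#' @return data.frame: decade bin, feature, mean absolute phi.
#' @export
attribution_by_decade <- function(attr, ages) {
  stopifnot(inherits(attr, "attribution_table"),
            length(ages) == nrow(attr$phi))
  bins <- .age_bins(ages, 10)
  used <- levels(bins)[tabulate(bins, nbins = nlevels(bins)) > 0]
  rows <- lapply(used, function(b) {
    m <- colMeans(abs(attr$phi[bins == b, , drop = FALSE]))
    data.frame(bin = b, feature = names(m), mean_abs_phi = as.numeric(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# histogram mutual information (bits) with equal-frequency bins
.mi_hist <- function(x, y, n_bins = 10) {
  bin_of <- function(v) {
    u <- unique(v)
    if (length(u) <= n_bins) return(match(v, sort(u)))
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  tab <- table(bin_of(x), bin_of(y))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / outer(px, py)[pos]))
}

#' Rescale eigenvectors by mutual information with a target
#'
#' Estimates the mutual information between each component's scores and a
#' target variable (histogram estimator on equal-frequency bins — a
#' documented stand-in with the right contract: non-negative, ~0 under
#' independence, invariant to monotone transforms of the score) and scales
#' each eigenvector by it.
#'
#' @param Q eigenvector matrix (features x components).
#' @param scores score matrix (samples x components), projections on `Q`.
#' @param target variable paired with the scores (non-constant).
#' @param n_bins number of equal-frequency bins (default 10).
#' @return list: `rescaled` eigenvectors, `mi` per component (bits).
#' @export
mi_rescale <- function(Q, scores, target, n_bins = 10) {
  scores <- as.matrix(scores)
  if (length(unique(target)) < 2) stop("constant target")
  if (ncol(Q) < ncol(scores)) stop("more score columns than eigenvectors")
  mi <- vapply(seq_len(ncol(scores)), function(k)
    max(.mi_hist(scores[, k], target, n_bins), 0), numeric(1))
  R <- Q[, seq_len(ncol(scores)), drop = FALSE] %*% diag(mi, length(mi))
  dimnames(R) <- dimnames(Q[, seq_len(ncol(scores)), drop = FALSE])
  list(rescaled = R, mi = setNames(mi, colnames(scores) %||%
                                     paste0("PC", seq_along(mi))))
}
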