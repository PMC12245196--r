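#' Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()]: exact enumeration for small samples
#' without ties, tie-corrected normal approximation otherwise.  The
#' reported statistic is U for the first sample.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default lets sample size decide (exact up to n = 50 per group, as in
#'   [stats::wilcox.test()]).
#' @return a `test_result` list: statistic, p, method, group sizes.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided", exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 method = "Mann-Whitney U",
                 n = c(length(x), length(y)),
                 alternative = alternative),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param alpha family-wise error rate for the rejection set.
#' @return list with `adjusted` p-values (monotone, capped at 1) and the
#'   logical `rejected` vector.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= alpha)
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA on absolute deviations from the group centers.  Classical
#' Levene centers at the group mean; `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param groups list of numeric vectors (`>= 2` groups, each with `>= 2`
#'   members).
#' @param center `"mean"` (classical, default) or `"median"`.
#' @return a `test_result` with the F statistic and p-value.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 members")
  cfun <- if (center == "mean") mean else stats::median
  z <- unlist(lapply(groups, function(g) abs(g - cfun(g))))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  av <- stats::anova(stats::lm(z ~ g))
  structure(list(statistic = av[["F value"]][1], p = av[["Pr(>F)"]][1],
                 df = c(av$Df[1], av$Df[2]),
                 method = paste0("Levene (", center, "-centered)"),
                 n = vapply(groups, length, 1L)),
            class = "test_result")
}

#' Compare aging slopes across groups
#'
#' OLS of predicted on chronological age with group interaction terms:
#' reports the reference group's slope, each other group's additional
#' slope, and the interaction t-test p-value.
#'
#' @param predicted,chronological numeric vectors (years).
#' @param group_labels group label per sample.
#' @param reference_group label of the reference group (`>= 3` samples).
#' @return list: `reference_slope`, and a data.frame `groups` with columns
#'   group, slope_delta, p.
#' @export
slope_comparison <- function(predicted, chronological, group_labels,
                             reference_group = "WND") {
  g <- stats::relevel(factor(group_labels), ref = reference_group)
  if (sum(g == reference_group) < 3)
    stop("reference group needs at least 3 samples")
  if (nlevels(g) == 1) {           # reduces to simple OLS
    fit <- stats::lm(predicted ~ chronological)
    sm <- summary(fit)$coefficients
    return(list(reference_slope = sm["chronological", "Estimate"],
                reference_intercept = sm["(Intercept)", "Estimate"],
                groups = NULL))
  }
  fit <- stats::lm(predicted ~ chronological * g)
  sm <- summary(fit)$coefficients
  if (any(is.na(coef(fit))))
    stop("singular design (constant age within a group?)")
  ref_slope <- sm["chronological", "Estimate"]
  others <- setdiff(levels(g), reference_group)
  rows <- lapply(others, function(gl) {
    term <- paste0("chronological:g", gl)
    data.frame(group = gl, slope_delta = sm[term, "Estimate"],
               p = sm[term, "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  list(reference_slope = ref_slope,
       reference_intercept = sm["(Intercept)", "Estimate"],
       groups = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Pearson correlation with test
#'
#' @param x,y paired numeric vectors (`>= 3` complete pairs, nonzero
#'   variance).
#' @return list `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
    stop("zero variance")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Pairwise Pearson correlation matrix
#'
#' @param features numeric matrix, variables in columns; pairwise-complete
#'   observations.  Zero-variance columns yield `NA` with a warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  features <- as.matrix(features)
  v <- apply(features, 2, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE))
    warning("zero-variance feature(s): ",
            paste(colnames(features)[which(v == 0)], collapse = ", "),
            "; correlations reported as NA")
  suppressWarnings(r <- stats::cor(features, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Per-lipid log2 fold change between two groups
#'
#' `log2(mean_b / mean_a)` on raw (untransformed) concentrations.
#'
#' @param group_a,group_b matrices (samples x lipids) or vectors on the raw
#'   concentration scale.
#' @return named numeric vector; non-positive group means give `NA` with a
#'   warning.
#' @export
log_fold_change <- function(group_a, group_b) {
  gmean <- function(g) if (is.null(dim(g))) mean(g, na.rm = TRUE)
    else colMeans(g, na.rm = TRUE)
  ma <- gmean(group_a)
  mb <- gmean(group_b)
  bad <- ma <= 0 | mb <= 0
  out <- log2(mb / ma)
  if (any(bad, na.rm = TRUE)) {
    warning("non-positive group mean(s); fold change reported as NA")
    out[bad] <- NA_real_
  }
  out
}
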