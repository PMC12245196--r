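#' Residual age acceleration and group comparisons
#'
#' Fits the expected aging trajectory — the ordinary least-squares line of
#' predicted on chronological age — on the reference (healthy) group only,
#' then measures every sample's deviation from that line.  Positive
#' residuals mean a sample looks biologically older than expected.  Each
#' disorder group is compared with the reference by a two-sided
#' Mann-Whitney U test on the residuals, with Holm-Bonferroni adjustment
#' across groups.
#'
#' @param predicted predicted ages (years).
#' @param chronological chronological (standardized) ages (years).
#' @param groups group labels, same length; must contain `reference`.
#' @param reference the reference group label (default `"WND"`).
#' @return object of class `acceleration_report`: per-sample residuals
#'   `delta`, the reference regression `line` (intercept, slope), and a
#'   `tests` table with adjusted p-values.
#' @export
compute_age_acceleration <- function(predicted, chronological, groups,
                                     reference = "WND") {
  stopifnot(length(predicted) == length(chronological),
            length(predicted) == length(groups))
  ref <- groups == reference
  if (sum(ref) < 3) stop("need at least 3 reference samples")
  if (stats::var(chronological[ref]) == 0)
    stop("degenerate (constant) chronological ages in reference group")
  fit <- stats::lm(predicted[ref] ~ chronological[ref])
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  delta <- predicted - (a + b * chronological)

  others <- setdiff(unique(groups), reference)
  tests <- NULL
  if (length(others)) {
    rows <- lapply(others, function(g) {
      mw <- mann_whitney_u(delta[groups == g], delta[ref])
      data.frame(group = g, n = sum(groups == g), n_ref = sum(ref),
                 statistic = mw$statistic, p = mw$p,
                 median_delta = stats::median(delta[groups == g]),
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, rows)
    hb <- holm_bonferroni(tests$p)
    tests$p_adjusted <- hb$adjusted
    tests <- tests[order(tests$group), , drop = FALSE]
    rownames(tests) <- NULL
  }
  structure(list(delta = delta, line = c(intercept = a, slope = b),
                 reference = reference, tests = tests),
            class = "acceleration_report")
}

#' @export
print.acceleration_report <- function(x, ...) {
  cat("acceleration_report (reference:", x$reference, ")\n")
  cat(sprintf("  expected trajectory: predicted = %.3f + %.3f * age\n",
              x$line["intercept"], x$line["slope"]))
  if (!is.null(x$tests)) {
    cat("  group comparisons (Mann-Whitney vs reference, Holm-adjusted):\n")
    print(format(x$tests, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
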