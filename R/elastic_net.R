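#' Fit an elastic-net regression
#'
#' Minimizes `(1/2n) * RSS + strength * (mixing * ||b||_1 +
#' (1 - mixing)/2 * ||b||_2^2)` with an unpenalized intercept — the same
#' parameterization as the reference scikit-learn / glmnet objective, so
#' `strength = 1, mixing = 0.5` reproduces the conventional defaults.
#' Solved by [glmnet::glmnet()] (predictors are not re-standardized: the
#' clock feeds already-normalized features); single-predictor designs use
#' the closed-form soft-threshold solution.
#'
#' @param X numeric design matrix without missing entries.
#' @param y response (ages, years); `length(y) == nrow(X) >= 2`.
#' @param mixing L1 share of the penalty, in `[0, 1]`.
#' @param strength overall regularization strength, `>= 0`.
#' @param penalty_factor optional per-column penalty multipliers (0 leaves a
#'   column unpenalized).
#' @return list with named `beta` and `intercept`.
#' @export
fit_elastic_net <- function(X, y, mixing = 0.5, strength = 1.0,
                            penalty_factor = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < 2) stop("need at least 2 observations")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  if (stats::var(y) == 0 && strength > 0) {
    return(list(beta = setNames(rep(0, ncol(X)), cn), intercept = mean(y)))
  }

  if (ncol(X) == 1) {
    pf <- if (is.null(penalty_factor)) 1 else penalty_factor[1]
    n <- nrow(X)
    xc <- X[, 1] - mean(X[, 1]); yc <- y - mean(y)
    rho <- sum(xc * yc) / n
    l1 <- strength * mixing * pf
    l2 <- strength * (1 - mixing) * pf
    denom <- sum(xc^2) / n + l2
    if (denom == 0) stop("degenerate single-column design")
    b <- sign(rho) * max(abs(rho) - l1, 0) / denom
    return(list(beta = setNames(b, cn),
                intercept = mean(y) - b * mean(X[, 1])))
  }

  lam <- max(strength, 1e-10)
  fit <- glmnet::glmnet(X, y, alpha = mixing,
                        lambda = lam * c(32, 8, 2, 1),
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7,
                        penalty.factor = penalty_factor %||%
                          rep(1, ncol(X)))
  cf <- as.numeric(coef(fit, s = lam))
  list(beta = setNames(cf[-1], cn), intercept = cf[1])
}
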