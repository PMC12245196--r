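#' Fit a lipidomic aging clock
#'
#' The core model: an elastic-net regression of standardized chronological
#' age on lipid features plus demographic covariates.  In
#' `"dolichols_only"` mode the features are the dolichol-flagged lipids
#' after K-nearest-neighbour imputation, Yeo-Johnson normalization and
#' scaling; in `"pca_all_lipids"` mode the full panel is transformed the
#' same way and projected onto the leading principal components of its
#' correlation matrix.  Sex and ethnicity enter one-hot encoded (first
#' level dropped), post-mortem interval as a scaled numeric covariate.
#'
#' @param dataset training [lipidomics_dataset()] (callers normally pass
#'   healthy/WND samples only).
#' @param feature_mode `"dolichols_only"` or `"pca_all_lipids"`.
#' @param covariates subset of `c("sex", "ethnicity", "pmi")`.
#' @param mixing,strength elastic-net penalty (see [fit_elastic_net()]);
#'   the defaults are the conventional elastic-net defaults.
#' @param n_pcs number of principal components (PCA mode); default keeps
#'   components explaining `pca_var` cumulative variance.
#' @param pca_var cumulative-variance target when `n_pcs` is `NULL`.
#' @param knn_k imputation neighbour count.
#' @param unpenalized_covariates if `TRUE`, covariates carry no penalty
#'   (they enter as free adjustments rather than penalized features).
#' @return an object of class `lipid_clock` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
#' @export
lipid_clock <- function(dataset,
                        feature_mode = c("dolichols_only", "pca_all_lipids"),
                        covariates = c("sex", "ethnicity", "pmi"),
                        mixing = 0.5, strength = 1.0,
                        n_pcs = NULL, pca_var = 0.95, knn_k = 5,
                        unpenalized_covariates = FALSE) {
  feature_mode <- match.arg(feature_mode)
  covariates <- if (is.null(covariates) || !length(covariates)) character(0)
    else match.arg(covariates, c("sex", "ethnicity", "pmi"),
                   several.ok = TRUE)

  lip_keep <- if (feature_mode == "dolichols_only")
    which(dataset$lipids$is_dolichol) else seq_len(nrow(dataset$lipids))
  if (feature_mode == "dolichols_only" && length(lip_keep) == 0)
    stop("dolichols_only mode requires at least one dolichol-flagged lipid")

  feat_ds <- subset_dataset(dataset, lipids = lip_keep)
  state <- fit_transform(feat_ds, k = knn_k)
  Z <- apply_transform(state, dataset)$values

  pca <- NULL
  if (feature_mode == "pca_all_lipids") {
    pca <- fit_pca(Z)
    if (is.null(n_pcs)) n_pcs <- pca_n_components(pca, pca_var)
    feats <- pca_project(pca, Z, n_pcs)
  } else {
    feats <- Z
  }

  enc <- .fit_covariate_encoding(dataset$samples, covariates)
  C <- .encode_covariates(enc, dataset$samples)
  X <- cbind(feats, C)
  y <- dataset$samples$standardized_age

  pf <- c(rep(1, ncol(feats)),
          rep(if (unpenalized_covariates) 0 else 1, ncol(C)))
  en <- fit_elastic_net(X, y, mixing = mixing, strength = strength,
                        penalty_factor = pf)
  fitted_ages <- as.numeric(en$intercept + X %*% en$beta)

  structure(list(feature_mode = feature_mode, transform = state, pca = pca,
                 n_pcs = n_pcs, beta = en$beta, intercept = en$intercept,
                 covariates = covariates, encoding = enc,
                 mixing = mixing, strength = strength,
                 X_train = X, train_ages = y, train_fitted = fitted_ages,
                 train_mae = stats::median(abs(fitted_ages - y)),
                 n_train = nrow(X)),
            class = "lipid_clock")
}

.fit_covariate_encoding <- function(samples, covariates) {
  enc <- list(covariates = covariates)
  if ("sex" %in% covariates)
    enc$sex_levels <- sort(unique(as.character(samples$sex)))
  if ("ethnicity" %in% covariates)
    enc$ethnicity_levels <- sort(unique(as.character(samples$ethnicity)))
  if ("pmi" %in% covariates) {
    enc$pmi_center <- mean(samples$pmi)
    s <- stats::sd(samples$pmi)
    enc$pmi_scale <- if (is.na(s) || s == 0) 1 else s
  }
  enc
}

.onehot <- function(x, levels, prefix) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad))
    stop("unseen ", prefix, " level(s): ", paste(bad, collapse = ", "))
  out <- vapply(levels[-1], function(l) as.numeric(x == l),
                numeric(length(x)))
  out <- matrix(out, nrow = length(x),
                dimnames = list(NULL, paste0(prefix, levels[-1])))
  out
}

.encode_covariates <- function(enc, samples) {
  mats <- list()
  if ("sex" %in% enc$covariates)
    mats$sex <- .onehot(samples$sex, enc$sex_levels, "sex")
  if ("ethnicity" %in% enc$covariates)
    mats$eth <- .onehot(samples$ethnicity, enc$ethnicity_levels, "ethnicity")
  if ("pmi" %in% enc$covariates)
    mats$pmi <- matrix((samples$pmi - enc$pmi_center) / enc$pmi_scale,
                       ncol = 1, dimnames = list(NULL, "pmi"))
  if (!length(mats))
    return(matrix(0, nrow(samples), 0))
  do.call(cbind, mats)
}

# feature matrix for a dataset under a fitted clock
.clock_design <- function(model, dataset) {
  Z <- apply_transform(model$transform, dataset)$values
  feats <- if (model$feature_mode == "pca_all_lipids")
    pca_project(model$pca, Z, model$n_pcs) else Z
  C <- .encode_covariates(model$encoding, dataset$samples)
  cbind(feats, C)
}

#' Predict ages with a fitted clock
#'
#' @param object a [lipid_clock()].
#' @param newdata a [lipidomics_dataset()] covering the model's lipids; an
#'   unseen sex/ethnicity level is an error.
#' @param ... unused.
#' @return named numeric vector of predicted standardized ages (years).
#' @export
predict.lipid_clock <- function(object, newdata, ...) {
  X <- .clock_design(object, newdata)
  setNames(as.numeric(object$intercept + X %*% object$beta),
           newdata$samples$sample_id)
}

#' @export
coef.lipid_clock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
fitted.lipid_clock <- function(object, ...) object$train_fitted

#' @export
residuals.lipid_clock <- function(object, ...)
  object$train_ages - object$train_fitted

#' @export
print.lipid_clock <- function(x, ...) {
  cat("lipid_clock (", x$feature_mode, ")\n", sep = "")
  cat(sprintf("  trained on %d samples; %d features (%d nonzero)\n",
              x$n_train, length(x$beta), sum(x$beta != 0)))
  cat(sprintf("  penalty: mixing %.2f, strength %.3g\n",
              x$mixing, x$strength))
  cat(sprintf("  training median absolute error: %.2f years\n", x$train_mae))
  invisible(x)
}

#' @export
summary.lipid_clock <- function(object, ...) {
  nz <- object$beta[object$beta != 0]
  out <- list(model = object,
              nonzero = nz[order(-abs(nz))],
              train_mae = object$train_mae,
              train_r = stats::cor(object$train_fitted, object$train_ages))
  class(out) <- "summary.lipid_clock"
  out
}

#' @export
print.summary.lipid_clock <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training r(predicted, age): %.3f\n", x$train_r))
  cat("  leading coefficients:\n")
  print(round(utils::head(x$nonzero, 10), 4))
  invisible(x)
}

#' @export
plot.lipid_clock <- function(x, ...) {
  plot(x$train_ages, x$train_fitted,
       xlab = "chronological age (years)",
       ylab = "predicted age (years)",
       main = "lipid clock: training fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
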