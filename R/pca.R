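#' PCA via correlation-matrix eigendecomposition
#'
#' Decomposes the feature correlation matrix as `S = Q L Q^T`.  Eigenvector
#' signs are fixed so the largest-magnitude loading of each component is
#' positive, making results deterministic.  Zero-variance features are
#' dropped with a warning.
#'
#' @param X numeric matrix, samples in rows (`>= 2`), no missing values.
#' @return object of class `lipid_pca`: orthonormal eigenvectors `Q`,
#'   non-increasing eigenvalues `lambda` (summing to the number of retained
#'   features), and the centering/scaling used for projection.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  S <- stats::cor(X)
  e <- eigen(S, symmetric = TRUE)
  Q <- e$vectors
  for (k in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, k]))
    if (Q[i, k] < 0) Q[, k] <- -Q[, k]
  }
  rownames(Q) <- colnames(X)
  colnames(Q) <- paste0("PC", seq_len(ncol(Q)))
  structure(list(Q = Q, lambda = pmax(e$values, 0),
                 center = colMeans(X), scale = apply(X, 2, stats::sd),
                 features = colnames(X)),
            class = "lipid_pca")
}

#' Project samples onto fitted principal components
#'
#' @param pca a [fit_pca()] object.
#' @param X matrix with the pca's features (matched by column name when
#'   present).
#' @param n_pcs number of leading components (default: all).
#' @return score matrix (samples x components).
#' @export
pca_project <- function(pca, X, n_pcs = NULL) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    idx <- match(pca$features, colnames(X))
    if (any(is.na(idx))) stop("X lacks feature(s): ",
                              paste(pca$features[is.na(idx)], collapse = ", "))
    X <- X[, idx, drop = FALSE]
  }
  Z <- sweep(sweep(X, 2, pca$center), 2, pca$scale, "/")
  m <- n_pcs %||% ncol(pca$Q)
  Z %*% pca$Q[, seq_len(m), drop = FALSE]
}

#' Components needed to reach a cumulative-variance target
#'
#' @param pca a [fit_pca()] object.
#' @param var_explained cumulative proportion of variance, in (0, 1].
#' @return the smallest number of leading components reaching the target.
#' @export
pca_n_components <- function(pca, var_explained = 0.95) {
  which(cumsum(pca$lambda) / sum(pca$lambda) >= var_explained)[1]
}
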