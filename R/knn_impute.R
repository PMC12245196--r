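# K-nearest-neighbour imputation with nan-Euclidean distances.
# Distances are computed on mutually observed lipids, rescaled by the
# fraction observed; a cell is imputed as the unweighted mean of the k
# nearest donor samples that have that lipid observed.  Observed values are
# never altered.

# scaled squared distance between one query row and every reference row
.nan_dist <- function(q, ref) {
  p <- length(q)
  qm <- matrix(q, nrow(ref), p, byrow = TRUE)
  diff2 <- (qm - ref)^2
  shared <- !is.na(diff2)
  ns <- rowSums(shared)
  diff2[!shared] <- 0
  d2 <- rowSums(diff2) * p / pmax(ns, 1)
  d2[ns == 0] <- Inf
  sqrt(d2)
}

# impute missing cells of `x` using donor rows of `ref` (both raw matrices).
# When a row of x is also a row of ref it never donates to itself: its own
# missing cells are NA in ref too, so it is excluded per-feature.
.knn_impute <- function(x, ref, k) {
  out <- x
  for (i in which(rowSums(is.na(x)) > 0)) {
    d <- .nan_dist(x[i, ], ref)
    ord <- order(d, seq_along(d))   # deterministic tie-break by donor index
    for (j in which(is.na(x[i, ]))) {
      donors <- ord[!is.na(ref[ord, j])]
      if (!length(donors))
        stop("no donor with observed values for lipid '",
             colnames(x)[j], "'")
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(ref[use, j])
    }
  }
  out
}
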