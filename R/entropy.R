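#' Fit the reference model for lipid-profile binarization
#'
#' Anchors the entropy statistics to a healthy reference window
#' (standardized ages 20-40, reference-group samples only), under the
#' assumption of stable prefrontal-cortex lipid regulation in that window.
#' A per-lipid Yeo-Johnson transform is fitted on the window samples, and
#' each lipid's post-transform mean and sd on the window define the
#' "normal" band used by [binarize()].
#'
#' @param dataset a [lipidomics_dataset()].
#' @param age_window standardized-age window (years), default `c(20, 40)`.
#' @param threshold deviation threshold in sd units (`> 0`), default 2.
#' @param reference_group diagnosis label of the healthy reference
#'   (default `"WND"`); other samples inside the window are excluded and
#'   their count reported.
#' @return object of class `reference_model`.
#' @export
fit_reference <- function(dataset, age_window = c(20, 40), threshold = 2,
                          reference_group = "WND") {
  if (threshold <= 0) stop("threshold must be > 0")
  in_win <- dataset$samples$standardized_age >= age_window[1] &
    dataset$samples$standardized_age <= age_window[2]
  is_ref <- dataset$samples$diagnosis == reference_group
  n_excl <- sum(in_win & !is_ref)
  if (n_excl > 0)
    message("fit_reference: excluded ", n_excl,
            " non-", reference_group, " sample(s) from the window")
  keep <- in_win & is_ref
  if (!any(keep)) stop("reference window is empty")
  if (sum(keep) < 10)
    warning("only ", sum(keep), " reference samples in the window")
  x <- dataset$values[keep, , drop = FALSE]
  lambda <- apply(x, 2, yj_lambda)
  z <- x
  for (j in seq_len(ncol(z))) z[, j] <- yeo_johnson(x[, j], lambda[j])
  mu <- colMeans(z, na.rm = TRUE)
  sdv <- apply(z, 2, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  structure(list(lambda = lambda, mean = mu, sd = sdv,
                 threshold = threshold, age_window = age_window,
                 reference_group = reference_group,
                 lipid_names = colnames(dataset$values),
                 n_reference = sum(keep)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("reference_model:", length(x$lipid_names), "lipids,",
      x$n_reference, "reference samples\n")
  cat(sprintf("  window: %g-%g years (%s), threshold %g sd\n",
              x$age_window[1], x$age_window[2], x$reference_group,
              x$threshold))
  invisible(x)
}

# restrict a reference model to a subset of its lipids
.subset_reference <- function(ref, names) {
  idx <- match(names, ref$lipid_names)
  if (any(is.na(idx)))
    stop("reference model lacks lipid(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  ref$lambda <- ref$lambda[idx]
  ref$mean <- ref$mean[idx]
  ref$sd <- ref$sd[idx]
  ref$lipid_names <- ref$lipid_names[idx]
  ref
}

#' Binarize lipid profiles against the reference distribution
#'
#' A cell is 1 when its Yeo-Johnson-transformed value deviates *strictly*
#' beyond `threshold` reference standard deviations from the reference
#' mean, 0 otherwise.  Missing cells count as 0 (no observed deviation);
#' their number is reported.
#'
#' @param ref a [fit_reference()] model.
#' @param dataset a [lipidomics_dataset()] with the reference's lipids.
#' @return integer 0/1 matrix `D` (samples x lipids).
#' @export
binarize <- function(ref, dataset) {
  stopifnot(inherits(ref, "reference_model"))
  idx <- match(ref$lipid_names, dataset$lipids$name)
  if (any(is.na(idx)))
    stop("dataset lacks lipid(s): ",
         paste(ref$lipid_names[is.na(idx)], collapse = ", "))
  x <- dataset$values[, idx, drop = FALSE]
  D <- matrix(0L, nrow(x), ncol(x),
              dimnames = list(dataset$samples$sample_id, ref$lipid_names))
  for (j in seq_len(ncol(x))) {
    z <- yeo_johnson(x[, j], ref$lambda[j])
    dev <- abs(z - ref$mean[j]) > ref$threshold * ref$sd[j]
    D[, j] <- as.integer(!is.na(dev) & dev)
  }
  nmiss <- sum(is.na(x))
  if (nmiss > 0)
    message("binarize: ", nmiss, " missing cell(s) treated as no deviation")
  D
}

# assign ages to left-closed bins [lo, lo + width)
.age_bins <- function(ages, bin_width) {
  lo <- floor(min(ages) / bin_width) * bin_width
  hi <- ceiling(max(ages) / bin_width) * bin_width
  if (hi == max(ages)) hi <- hi + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cut(ages, breaks = breaks, right = FALSE, include.lowest = FALSE)
}

# binary Shannon entropy in bits, with 0*log 0 == 0
binary_entropy <- function(f) {
  h <- numeric(length(f))
  ok <- !is.na(f) & f > 0 & f < 1
  h[ok] <- -f[ok] * log2(f[ok]) - (1 - f[ok]) * log2(1 - f[ok])
  h[is.na(f)] <- NA_real_
  h
}

#' Group-level entropy within age bins
#'
#' For every age bin and lipid, the proportion `f` of samples deviating
#' (per the binary matrix `D`) gives a per-lipid binary entropy
#' `h = -f log2 f - (1-f) log2(1-f)`; the bin's group entropy is the mean
#' of `h` over lipids (mean, not sum, so panels of different size are
#' comparable).
#'
#' @param D binary deviation matrix from [binarize()].
#' @param ages standardized ages, one per row of `D`.
#' @param bin_width bin width in years (default 10).
#' @return list: `summary` data.frame (bin, n, H_group in bits),
#'   `per_lipid_h` (bins x lipids entropy matrix) and `frequency`
#'   (bins x lipids deviation proportions).  Empty bins are absent.
#' @export
group_entropy <- function(D, ages, bin_width = 10) {
  stopifnot(nrow(D) == length(ages))
  bins <- .age_bins(ages, bin_width)
  used <- levels(bins)[tabulate(bins, nbins = nlevels(bins)) > 0]
  f <- t(vapply(used, function(b) colMeans(D[bins == b, , drop = FALSE]),
                numeric(ncol(D))))
  h <- t(apply(f, 1, binary_entropy))
  dimnames(f) <- dimnames(h) <- list(used, colnames(D))
  list(summary = data.frame(bin = used,
                            n = as.integer(table(bins)[used]),
                            H_group = rowMeans(h),
                            row.names = NULL),
       per_lipid_h = h, frequency = f)
}

#' Reference deviation frequencies per age bin
#'
#' The proportion of healthy (reference-group) samples in each age bin
#' that deviate for each lipid, clipped to `[eps, 1-eps]` with
#' `eps = 1/(2 n_bin)` so rare deviations keep finite surprisal.
#'
#' @param D binary deviation matrix.
#' @param ages standardized ages.
#' @param diagnosis diagnosis labels.
#' @param bin_width age-bin width in years.
#' @param reference_group healthy group label.
#' @return list: `frequency` (bins x lipids, clipped), `n` reference count
#'   per bin, and the bin factor `bins` for the input samples.
#' @export
reference_frequencies <- function(D, ages, diagnosis, bin_width = 10,
                                  reference_group = "WND") {
  bins <- .age_bins(ages, bin_width)
  ref <- diagnosis == reference_group
  lv <- levels(bins)
  n_ref <- vapply(lv, function(b) sum(ref & bins == b), integer(1))
  f <- matrix(NA_real_, length(lv), ncol(D), dimnames = list(lv, colnames(D)))
  for (b in lv[n_ref > 0]) {
    fb <- colMeans(D[ref & bins == b, , drop = FALSE])
    eps <- 1 / (2 * sum(ref & bins == b))
    f[b, ] <- pmin(pmax(fb, eps), 1 - eps)
  }
  list(frequency = f, n = setNames(n_ref, lv), bins = bins)
}

# surprisal weights of one sample's deviating lipids
.deviation_weights <- function(drow, frow) {
  dev <- which(drow == 1)
  if (!length(dev)) return(numeric(0))
  w <- -log2(frow[dev])
  names(w) <- names(drow)[dev] %||% colnames(frow)
  w
}

#' Rarity-weighted individual entropy
#'
#' Per-sample entropy of the lipid profile's deviations, weighting each
#' deviating lipid by its rarity (surprisal, `-log2 f`) among healthy
#' references of the sample's own age bin.  In the default
#' `"weighted"` mode the surprisals are normalized to a distribution `q`
#' over the deviating lipids and `H = -sum(q log2 q)` bits (0 for no or a
#' single deviation); `"surprisal-sum"` instead returns the total
#' surprisal `sum(w)`.
#'
#' @param D binary deviation matrix.
#' @param ages,diagnosis per-sample metadata.
#' @param bin_width age-bin width in years.
#' @param mode `"weighted"` (default) or `"surprisal-sum"`.
#' @param reference_group healthy group label.
#' @return named numeric vector of per-sample entropies (bits).
#' @export
individual_entropy <- function(D, ages, diagnosis, bin_width = 10,
                               mode = c("weighted", "surprisal-sum"),
                               reference_group = "WND") {
  mode <- match.arg(mode)
  rf <- reference_frequencies(D, ages, diagnosis, bin_width, reference_group)
  H <- numeric(nrow(D))
  names(H) <- rownames(D)
  for (i in seq_len(nrow(D))) {
    b <- as.character(rf$bins[i])
    if (rf$n[b] == 0)
      stop("no ", reference_group, " reference members in age bin ", b)
    w <- .deviation_weights(D[i, ], rf$frequency[b, ])
    if (!length(w)) { H[i] <- 0; next }
    if (mode == "surprisal-sum") {
      H[i] <- sum(w)
    } else {
      q <- w / sum(w)
      H[i] <- -sum(q * log2(q))
    }
  }
  H
}

#' Top entropy-contributing lipid per sample
#'
#' The deviating lipid with the largest rarity weight (surprisal) for each
#' sample; ties break lexicographically by lipid name, samples without
#' deviations give `NA`.
#'
#' @inheritParams individual_entropy
#' @return character vector, one lipid name (or `NA`) per sample.
#' @export
entropy_contributors <- function(D, ages, diagnosis, bin_width = 10,
                                 reference_group = "WND") {
  rf <- reference_frequencies(D, ages, diagnosis, bin_width, reference_group)
  out <- rep(NA_character_, nrow(D))
  names(out) <- rownames(D)
  for (i in seq_len(nrow(D))) {
    b <- as.character(rf$bins[i])
    if (rf$n[b] == 0)
      stop("no ", reference_group, " reference members in age bin ", b)
    dev <- which(D[i, ] == 1)
    if (!length(dev)) next
    w <- -log2(rf$frequency[b, dev])
    nm <- colnames(D)[dev]
    ord <- order(-w, nm)
    out[i] <- nm[ord[1]]
  }
  out
}

#' Dolichol-only individual entropy
#'
#' [individual_entropy()] restricted to the dolichol-flagged lipids: the
#' reference model is sliced to the dolichol panel, deviations are
#' re-binarized on that submatrix and entropy recomputed.  Identical to
#' the full statistic when every lipid is a dolichol.
#'
#' @param dataset a [lipidomics_dataset()] with `>= 2` dolichol lipids.
#' @param ref a [fit_reference()] model covering the dolichols.
#' @inheritParams individual_entropy
#' @return named numeric vector of per-sample dolichol entropies (bits).
#' @export
dolichol_entropy <- function(dataset, ref, bin_width = 10,
                             mode = c("weighted", "surprisal-sum"),
                             reference_group = "WND") {
  mode <- match.arg(mode)
  dol <- dataset$lipids$name[dataset$lipids$is_dolichol]
  if (length(dol) < 2) stop("need at least 2 dolichol lipids")
  sub_ref <- .subset_reference(ref, dol)
  D <- binarize(sub_ref, dataset)
  individual_entropy(D, dataset$samples$standardized_age,
                     dataset$samples$diagnosis, bin_width, mode,
                     reference_group)
}
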