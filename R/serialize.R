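#' Serialize a fitted clock to JSON
#'
#' Writes everything needed to reload and apply the model elsewhere:
#' elastic-net coefficients and intercept, the fitted transform state
#' (imputation neighbours, per-lipid lambda/center/scale and the raw
#' training matrix backing KNN donors), any PCA basis, and the covariate
#' encoding.  Numbers are written at full precision.
#'
#' @param model a [lipid_clock()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clock_json <- function(model, path) {
  stopifnot(inherits(model, "lipid_clock"))
  st <- model$transform
  pca <- model$pca
  obj <- list(
    feature_mode = model$feature_mode,
    intercept = model$intercept,
    beta = as.list(model$beta),
    covariates = model$covariates,
    encoding = model$encoding,
    mixing = model$mixing, strength = model$strength,
    n_pcs = model$n_pcs,
    train_mae = model$train_mae, n_train = model$n_train,
    transform = list(k = st$k, lambda = as.list(st$lambda),
                     center = as.list(st$center), scale = as.list(st$scale),
                     lipid_names = st$lipid_names,
                     train_ids = st$train_ids,
                     train_raw = apply(st$train_raw, 1, as.list,
                                       simplify = FALSE)),
    pca = if (!is.null(pca))
      list(Q = apply(pca$Q, 2, as.list, simplify = FALSE),
           lambda = pca$lambda, center = as.list(pca$center),
           scale = as.list(pca$scale), features = pca$features))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

.named_num <- function(l) {
  out <- vapply(l, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                numeric(1))
  out
}

#' Reload a clock serialized with [write_clock_json()]
#'
#' @param path JSON file path.
#' @return a `lipid_clock` usable with [predict()], [linear_shap()] etc.
#'   (training-set summaries such as fitted values are not round-tripped).
#' @export
read_clock_json <- function(path) {
  o <- jsonlite::read_json(path)
  tr <- o$transform
  lipids <- unlist(tr$lipid_names)
  train_raw <- do.call(rbind, lapply(tr$train_raw, .named_num))
  dimnames(train_raw) <- list(unlist(tr$train_ids), lipids)
  state <- structure(list(k = tr$k, lambda = setNames(.named_num(tr$lambda),
                                                      lipids),
                          center = setNames(.named_num(tr$center), lipids),
                          scale = setNames(.named_num(tr$scale), lipids),
                          train_raw = train_raw, lipid_names = lipids,
                          train_ids = unlist(tr$train_ids)),
                     class = "transform_state")
  pca <- NULL
  if (!is.null(o$pca)) {
    feats <- unlist(o$pca$features)
    Q <- do.call(cbind, lapply(o$pca$Q, .named_num))
    dimnames(Q) <- list(feats, paste0("PC", seq_len(ncol(Q))))
    pca <- structure(list(Q = Q, lambda = as.numeric(unlist(o$pca$lambda)),
                          center = setNames(.named_num(o$pca$center), feats),
                          scale = setNames(.named_num(o$pca$scale), feats),
                          features = feats),
                     class = "lipid_pca")
  }
  enc <- o$encoding
  enc$covariates <- unlist(enc$covariates)
  if (!is.null(enc$sex_levels)) enc$sex_levels <- unlist(enc$sex_levels)
  if (!is.null(enc$ethnicity_levels))
    enc$ethnicity_levels <- unlist(enc$ethnicity_levels)
  structure(list(feature_mode = o$feature_mode, transform = state,
                 pca = pca, n_pcs = o$n_pcs,
                 beta = setNames(.named_num(o$beta), names(o$beta)),
                 intercept = o$intercept,
                 covariates = unlist(o$covariates), encoding = enc,
                 mixing = o$mixing, strength = o$strength,
                 train_mae = o$train_mae, n_train = o$n_train),
            class = "lipid_clock")
}
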