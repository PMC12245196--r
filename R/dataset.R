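#' Construct a lipidomics dataset
#'
#' The package's universal data currency: a samples x lipids concentration
#' matrix (missing values allowed) together with a per-sample metadata table
#' and a per-lipid annotation table.
#'
#' @param values numeric matrix, samples in rows, lipids in columns.
#'   Rownames are sample ids, colnames lipid names.
#' @param samples data.frame with columns `sample_id`, `reported_age`,
#'   `standardized_age`, `sex`, `ethnicity`, `pmi`, `diagnosis`.
#' @param lipids data.frame with columns `name`, `formula`, `lm_id`,
#'   `molecular_weight`, `retention_time`, `is_dolichol`.
#' @param ground_truth optional list with elements `samples` (per-sample
#'   biological age) and `lipids` (generating parameters); only present for
#'   synthetic cohorts.
#' @return an object of class `lipidomics_dataset`.
#' @export
lipidomics_dataset <- function(values, samples, lipids, ground_truth = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(samples))
    stop("values has ", nrow(values), " rows but samples has ",
         nrow(samples), " entries")
  if (ncol(values) != nrow(lipids))
    stop("values has ", ncol(values), " columns but lipids has ",
         nrow(lipids), " entries")
  need_s <- c("sample_id", "reported_age", "standardized_age", "sex",
              "ethnicity", "pmi", "diagnosis")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stop("samples table missing columns: ",
                         paste(miss, collapse = ", "))
  need_l <- c("name", "formula", "lm_id", "molecular_weight",
              "retention_time", "is_dolichol")
  miss <- setdiff(need_l, names(lipids))
  if (length(miss)) stop("lipids table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(stats::na.omit(samples$pmi) < 0)) stop("pmi must be >= 0")
  bad <- setdiff(unique(samples$diagnosis), diagnosis_levels())
  if (length(bad)) stop("unknown diagnosis level(s): ",
                        paste(bad, collapse = ", "))
  rownames(values) <- as.character(samples$sample_id)
  colnames(values) <- as.character(lipids$name)
  structure(list(values = values,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 lipids = as.data.frame(lipids, stringsAsFactors = FALSE),
                 ground_truth = ground_truth),
            class = "lipidomics_dataset")
}

diagnosis_levels <- function() c("WND", "ASD", "SZ", "DS")

#' @export
print.lipidomics_dataset <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat("lipidomics_dataset:", nrow(x$values), "samples x",
      ncol(x$values), "lipids\n")
  cat(sprintf("  missing cells: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  cat("  diagnosis:",
      paste(sprintf("%s=%d", names(table(x$samples$diagnosis)),
                    table(x$samples$diagnosis)), collapse = " "), "\n")
  cat("  dolichols:", sum(x$lipids$is_dolichol), "\n")
  if (!is.null(x$ground_truth)) cat("  ground truth: present\n")
  invisible(x)
}

#' @export
dim.lipidomics_dataset <- function(x) dim(x$values)

#' Subset a dataset by samples and/or lipids
#'
#' @param dataset a [lipidomics_dataset()].
#' @param samples,lipids logical or integer index vectors (default: keep all).
#' @return the subsetted `lipidomics_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, lipids = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(dataset$values)) else samples
  li <- if (is.null(lipids)) seq_len(ncol(dataset$values)) else lipids
  gt <- dataset$ground_truth
  if (!is.null(gt)) {
    if (!is.null(gt$samples)) gt$samples <- gt$samples[si, , drop = FALSE]
    if (!is.null(gt$lipids))  gt$lipids  <- gt$lipids[li, , drop = FALSE]
  }
  lipidomics_dataset(dataset$values[si, li, drop = FALSE],
                     dataset$samples[si, , drop = FALSE],
                     dataset$lipids[li, , drop = FALSE],
                     ground_truth = gt)
}

# full-precision numeric formatting so CSV round-trips are lossless
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

.df_full_precision <- function(df) {
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
  df
}

#' Write a dataset as the three-table CSV layout
#'
#' Writes `values.csv` (sample_id index + one column per lipid),
#' `samples.csv` and `lipids.csv` (plus `ground_truth_samples.csv` /
#' `ground_truth_lipids.csv` when present) into `dir`.  Numeric values are
#' written at full precision so the layout round-trips losslessly through
#' [read_dataset()].
#'
#' @param dataset a [lipidomics_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- as.data.frame(dataset$values)
  vals <- .df_full_precision(vals)
  vals <- cbind(sample_id = rownames(dataset$values), vals)
  utils::write.csv(vals, file.path(dir, "values.csv"), row.names = FALSE)
  utils::write.csv(.df_full_precision(dataset$samples),
                   file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(.df_full_precision(dataset$lipids),
                   file.path(dir, "lipids.csv"), row.names = FALSE)
  gt <- dataset$ground_truth
  if (!is.null(gt)) {
    if (!is.null(gt$samples))
      utils::write.csv(.df_full_precision(gt$samples),
                       file.path(dir, "ground_truth_samples.csv"),
                       row.names = FALSE)
    if (!is.null(gt$lipids))
      utils::write.csv(.df_full_precision(gt$lipids),
                       file.path(dir, "ground_truth_lipids.csv"),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset from the three-table CSV layout
#'
#' @param dir directory containing `values.csv`, `samples.csv`, `lipids.csv`
#'   as written by [write_dataset()].
#' @return a [lipidomics_dataset()].
#' @export
read_dataset <- function(dir) {
  vals <- utils::read.csv(file.path(dir, "values.csv"),
                          check.names = FALSE)
  ids <- vals$sample_id
  vals <- as.matrix(vals[, setdiff(names(vals), "sample_id"), drop = FALSE])
  rownames(vals) <- ids
  samples <- utils::read.csv(file.path(dir, "samples.csv"))
  lipids <- utils::read.csv(file.path(dir, "lipids.csv"))
  gt <- NULL
  fs <- file.path(dir, "ground_truth_samples.csv")
  fl <- file.path(dir, "ground_truth_lipids.csv")
  if (file.exists(fs) || file.exists(fl)) {
    gt <- list()
    if (file.exists(fs)) gt$samples <- utils::read.csv(fs)
    if (file.exists(fl)) gt$lipids <- utils::read.csv(fl)
  }
  lipidomics_dataset(vals, samples, lipids, ground_truth = gt)
}
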