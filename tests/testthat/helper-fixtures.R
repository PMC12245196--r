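# fixtures built in code; no stored data

# minimal dataset from a values matrix plus whatever metadata is supplied
make_tiny_dataset <- function(values, ages = NULL, sex = NULL,
                              ethnicity = NULL, pmi = NULL,
                              diagnosis = NULL, is_dolichol = NULL,
                              lipids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("lip%02d", seq_len(p))
  ages <- ages %||% seq(25, 75, length.out = n)
  samples <- data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    reported_age = ages + 0.767,
    standardized_age = ages,
    sex = sex %||% rep(c("F", "M"), length.out = n),
    ethnicity = ethnicity %||% rep("Other", n),
    pmi = pmi %||% rep(12, n),
    diagnosis = diagnosis %||% rep("WND", n),
    stringsAsFactors = FALSE)
  if (is.null(lipids))
    lipids <- data.frame(
      name = colnames(values),
      formula = sprintf("C%dH%dO", 10 + seq_len(p), 20 + seq_len(p)),
      lm_id = sprintf("LMTEST%04d", seq_len(p)),
      molecular_weight = 300 + 10 * seq_len(p),
      retention_time = seq_len(p),
      is_dolichol = is_dolichol %||% rep(FALSE, p),
      stringsAsFactors = FALSE)
  lipidomics_dataset(values, samples, lipids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast synthetic configuration for pipeline-level tests
small_config <- function(...) {
  args <- list(n_samples = 60L, n_lipids = 12L, n_dolichols = 4L,
               group_fractions = c(WND = 0.8, ASD = 0.07, SZ = 0.11,
                                   DS = 0.02),
               n_ethnicity_lipids = 3L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}

# hand-built reference model with identity transform, for boundary tests
identity_reference <- function(lipid_names, threshold = 2) {
  p <- length(lipid_names)
  structure(list(lambda = rep(1, p), mean = setNames(rep(0, p), lipid_names),
                 sd = setNames(rep(1, p), lipid_names),
                 threshold = threshold, age_window = c(20, 40),
                 reference_group = "WND", lipid_names = lipid_names,
                 n_reference = 50L),
            class = "reference_model")
}
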