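#' Assemble a pipeline configuration
#'
#' Defaults follow the reference analysis wherever it states a value:
#' gestational offset 0.767 years, age window 20-80, KNN k = 5, 2-sd
#' deviation threshold, 10-year entropy bins, 5-year bootstrap strata, and
#' 10,000 bootstrap iterations (validation runs scale `n_iter` down).
#'
#' @param synthetic a [synthetic_config()] to generate the cohort, or
#'   `NULL` to read `input_dir` via [read_dataset()].
#' @param input_dir directory with the three-table CSV layout (used when
#'   `synthetic` is `NULL`).
#' @param seed root seed; each stage derives a named substream from it.
#' @param age_min,age_max standardized-age filter bounds (years).
#' @param knn_k imputation neighbour count.
#' @param outlier_pca_var,outlier_iqr_mult outlier-screen settings.
#' @param feature_mode,covariates,mixing,strength,n_pcs,unpenalized_covariates
#'   clock settings (see [lipid_clock()]).
#' @param n_iter bootstrap iterations.
#' @param entropy_window,entropy_threshold_sd,entropy_bin_width,entropy_mode
#'   entropy settings (see [fit_reference()], [individual_entropy()]).
#' @param stages named logical toggles: `preprocess`, `clock`, `entropy`,
#'   `stats`, `interpret`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL,
                            seed = 1L,
                            age_min = 20, age_max = 80,
                            knn_k = 5,
                            outlier_pca_var = 0.95, outlier_iqr_mult = 3,
                            feature_mode = "dolichols_only",
                            covariates = c("sex", "ethnicity", "pmi"),
                            mixing = 0.5, strength = 1.0, n_pcs = NULL,
                            unpenalized_covariates = FALSE,
                            n_iter = 10000,
                            entropy_window = c(20, 40),
                            entropy_threshold_sd = 2,
                            entropy_bin_width = 10,
                            entropy_mode = "weighted",
                            stages = list()) {
  st <- list(preprocess = TRUE, clock = TRUE, entropy = TRUE,
             stats = TRUE, interpret = TRUE)
  st[names(stages)] <- stages
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 seed = as.integer(seed),
                 age_min = age_min, age_max = age_max, knn_k = knn_k,
                 outlier_pca_var = outlier_pca_var,
                 outlier_iqr_mult = outlier_iqr_mult,
                 feature_mode = feature_mode, covariates = covariates,
                 mixing = mixing, strength = strength, n_pcs = n_pcs,
                 unpenalized_covariates = unpenalized_covariates,
                 n_iter = n_iter, entropy_window = entropy_window,
                 entropy_threshold_sd = entropy_threshold_sd,
                 entropy_bin_width = entropy_bin_width,
                 entropy_mode = entropy_mode, stages = st),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] arguments; a `synthetic` block is
#' passed to [synthetic_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$covariates)) y$covariates <- unlist(y$covariates)
  if (!is.null(y$entropy_window)) y$entropy_window <- unlist(y$entropy_window)
  do.call(pipeline_config, y)
}

.write_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes synthetic-data generation (or reading), preprocessing, the
#' bootstrap clock with age acceleration, the entropy battery, supporting
#' statistics and feature attribution, honoring the stage toggles, and
#' writes every intermediate artifact plus a machine-readable manifest to
#' `out_dir`.  Identical config and seed give identical outputs.  A stage
#' failure aborts with the stage named; artifacts written so far are kept.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output (run) directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- stage("input", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(config$seed, 10L)
      d <- generate_cohort(cfg)
      write_dataset(d, file.path(out_dir, "synthetic"))
      d
    } else read_dataset(config$input_dir)
  })

  outliers <- NULL
  if (config$stages$preprocess) {
    ds <- stage("preprocess", {
      d <- filter_age_range(ds, config$age_min, config$age_max)
      d <- resolve_duplicate_annotations(d)
      outliers <- detect_outliers(d, var_explained = config$outlier_pca_var,
                                   iqr_mult = config$outlier_iqr_mult)
      if (length(outliers$flagged))
        d <- subset_dataset(d,
                            samples = !d$samples$sample_id %in% outliers$flagged)
      .write_csv(data.frame(sample_id = names(outliers$mean_distance),
                            mean_distance = outliers$mean_distance,
                            flagged = names(outliers$mean_distance) %in%
                              outliers$flagged),
                 out_dir, "outliers.csv")
      .write_csv(d$samples, out_dir, "samples_preprocessed.csv")
      d
    })
  }

  model <- NULL; accel <- NULL; boot <- NULL
  if (config$stages$clock) {
    stage("clock", {
      boot <- run_bootstrap(ds, n_iter = config$n_iter,
                             seed = derive_seed(config$seed, 20L),
                             feature_mode = config$feature_mode,
                             covariates = config$covariates,
                             mixing = config$mixing,
                             strength = config$strength,
                             n_pcs = config$n_pcs,
                             knn_k = config$knn_k,
                             unpenalized_covariates =
                               config$unpenalized_covariates)
      model <- select_median_model(boot)
      pred <- predict(model, ds)
      accel <- compute_age_acceleration(pred,
                                         ds$samples$standardized_age,
                                         ds$samples$diagnosis)
      .write_csv(data.frame(iteration = seq_along(boot$mae),
                            oob_mae = boot$mae,
                            oob_fraction = boot$oob_fraction),
                 out_dir, "bootstrap_mae.csv")
      .write_csv(data.frame(sample_id = ds$samples$sample_id,
                            chronological = ds$samples$standardized_age,
                            predicted = pred, residual = accel$delta,
                            diagnosis = ds$samples$diagnosis),
                 out_dir, "predictions.csv")
      .write_csv(accel$tests, out_dir, "acceleration_tests.csv")
      .write_csv(data.frame(feature = names(coef(model)),
                            coefficient = as.numeric(coef(model))),
                 out_dir, "model_coefficients.csv")
      write_clock_json(model, file.path(out_dir, "model.json"))
    })
  }

  entropy_ref <- NULL
  if (config$stages$entropy) {
    stage("entropy", {
      entropy_ref <- fit_reference(ds, config$entropy_window,
                                    config$entropy_threshold_sd)
      D <- binarize(entropy_ref, ds)
      ge <- group_entropy(D, ds$samples$standardized_age,
                          config$entropy_bin_width)
      hi <- individual_entropy(D, ds$samples$standardized_age,
                               ds$samples$diagnosis,
                               config$entropy_bin_width,
                               mode = config$entropy_mode)
      hd <- dolichol_entropy(ds, entropy_ref, config$entropy_bin_width,
                             mode = config$entropy_mode)
      top <- entropy_contributors(D, ds$samples$standardized_age,
                                  ds$samples$diagnosis,
                                  config$entropy_bin_width)
      .write_csv(ge$summary, out_dir, "entropy_by_bin.csv")
      .write_csv(data.frame(sample_id = ds$samples$sample_id,
                            H_ind = hi, H_dolichol = hd,
                            top_contributor = top),
                 out_dir, "entropy_by_sample.csv")
    })
  }

  if (config$stages$stats) {
    stage("stats", {
      dol <- ds$values[, ds$lipids$is_dolichol, drop = FALSE]
      cm <- correlation_matrix(dol)
      utils::write.csv(cm, file.path(out_dir, "dolichol_correlation.csv"))
      rows <- list()
      if (!is.null(model)) {
        pred <- predict(model, ds)
        keep <- ds$samples$diagnosis != "DS"  # too few DS in range
        sc <- slope_comparison(pred[keep],
                               ds$samples$standardized_age[keep],
                               ds$samples$diagnosis[keep])
        rows$slopes <- data.frame(analysis = "slope_comparison",
                                  unit = c("WND", sc$groups$group),
                                  statistic = c(sc$reference_slope,
                                                sc$groups$slope_delta),
                                  p = c(NA, sc$groups$p))
      }
      age <- ds$samples$standardized_age
      young <- dol[age < 40, , drop = FALSE]
      old <- dol[age >= 40, , drop = FALSE]
      lev <- lapply(colnames(dol), function(l)
        levene_test(list(young[, l][!is.na(young[, l])],
                         old[, l][!is.na(old[, l])])))
      rows$levene <- data.frame(analysis = "levene_split40",
                                unit = colnames(dol),
                                statistic = vapply(lev, `[[`, 1, "statistic"),
                                p = vapply(lev, `[[`, 1, "p"))
      rows$levene$p_adjusted <- holm_bonferroni(rows$levene$p)$adjusted
      lfc <- log_fold_change(young, old)
      rows$lfc <- data.frame(analysis = "lfc_young_vs_old",
                             unit = names(lfc), statistic = lfc, p = NA)
      tab <- do.call(rbind, lapply(rows, function(r) {
        r$p_adjusted <- r$p_adjusted %||% NA
        r[, c("analysis", "unit", "statistic", "p", "p_adjusted")]
      }))
      .write_csv(tab, out_dir, "stats_tests.csv")
    })
  }

  if (config$stages$interpret && !is.null(model)) {
    stage("interpret", {
      attr <- linear_shap(model, ds)
      phi <- as.data.frame(attr$phi)
      phi <- cbind(sample_id = rownames(attr$phi), phi)
      .write_csv(phi, out_dir, "attributions.csv")
      .write_csv(attribution_by_decade(attr, ds$samples$standardized_age),
                 out_dir, "attributions_by_decade.csv")
      if (model$feature_mode == "pca_all_lipids") {
        imp <- pc_importance(model)
        .write_csv(data.frame(lipid = names(imp), importance = imp),
                   out_dir, "pc_importance.csv")
      }
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lipoclock")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    library_versions = list(
      glmnet = as.character(utils::packageVersion("glmnet")),
      jsonlite = as.character(utils::packageVersion("jsonlite"))),
    seed = config$seed,
    substream_seeds = list(synthetic = derive_seed(config$seed, 10L),
                           bootstrap = derive_seed(config$seed, 20L)),
    config = config[setdiff(names(config), "synthetic")],
    synthetic = if (!is.null(config$synthetic))
      unclass(config$synthetic),
    n_samples_analyzed = nrow(ds$values),
    n_lipids_analyzed = ncol(ds$values))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' Render a run directory as a markdown report
#'
#' Collates the per-stage CSV artifacts into a single `report.md`.
#' Missing artifacts are listed; the report still covers whatever stages
#' completed (an empty run directory is an error).
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return path of the report file, invisibly.
#' @export
make_report <- function(run_dir) {
  want <- c("entropy_by_bin.csv", "predictions.csv",
            "acceleration_tests.csv", "dolichol_correlation.csv",
            "attributions_by_decade.csv")
  have <- file.exists(file.path(run_dir, want))
  if (!any(have))
    stop("no artifacts found in ", run_dir, "; missing: ",
         paste(want, collapse = ", "))
  lines <- c("# Pipeline report", "")
  if (any(!have))
    lines <- c(lines, paste("Missing artifacts:",
                            paste(want[!have], collapse = ", ")), "")
  fmt_table <- function(df) {
    df <- utils::head(df, 25)
    txt <- apply(df, 1, function(r) paste(r, collapse = " | "))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "), txt, "")
  }
  add <- function(lines, file, title) {
    if (!file.exists(file.path(run_dir, file))) return(lines)
    df <- utils::read.csv(file.path(run_dir, file), check.names = FALSE)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 5))
    c(lines, paste("##", title), "", fmt_table(df))
  }
  lines <- add(lines, "entropy_by_bin.csv", "Group entropy by age bin")
  lines <- add(lines, "predictions.csv", "Predicted vs chronological age")
  lines <- add(lines, "acceleration_tests.csv",
               "Age acceleration by diagnosis group")
  lines <- add(lines, "dolichol_correlation.csv",
               "Dolichol correlation matrix")
  lines <- add(lines, "attributions_by_decade.csv",
               "Mean |attribution| by decade")
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
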