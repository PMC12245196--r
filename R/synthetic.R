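#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the post-mortem
#' prefrontal-cortex lipidome the clocks were designed for: 242 samples,
#' 163 lipid features, ~2% missing cells, group composition 195 healthy
#' (WND) : 15 autism (ASD) : 27 schizophrenia (SZ) : 5 Down syndrome (DS),
#' dolichol species increasing linearly with age with age-growing variance,
#' additive age-acceleration offsets in the disorder groups, and an
#' ethnicity-correlated mean shift on a subset of lipids.
#'
#' @param n_samples number of samples.
#' @param age_range chronological (standardized) age range, years.
#' @param group_fractions named proportions over WND/ASD/SZ/DS; must sum
#'   to 1.
#' @param n_lipids,n_dolichols feature counts (`n_dolichols <= n_lipids`).
#' @param dolichol_slope expected concentration increase per year of
#'   biological age.
#' @param dolichol_var_growth per-decade growth of the dolichol noise sd:
#'   `sd(age) = noise_sd * (1 + dolichol_var_growth * (age - 20)/10)`.
#' @param accel_offsets named years added to the biological-age signal per
#'   group (the ground-truth age acceleration).
#' @param ethnicity_levels,ethnicity_fractions population structure.
#' @param ethnicity_effect additive mean shift (concentration units) applied
#'   to `n_ethnicity_lipids` non-dolichol lipids, signed by ethnicity.
#' @param n_ethnicity_lipids how many lipids carry the ethnicity shift.
#' @param missing_rate proportion of cells set missing completely at random,
#'   in `[0, 1)`.
#' @param noise_sd baseline measurement noise sd (concentration units).
#' @param age_jitter_sd sd (years) of the individual biological-age jitter.
#' @param seed integer; identical configs give byte-identical cohorts.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 242L,
                             age_range = c(20, 80),
                             group_fractions = c(WND = 195, ASD = 15,
                                                 SZ = 27, DS = 5) / 242,
                             n_lipids = 163L,
                             n_dolichols = 6L,
                             dolichol_slope = 0.5,
                             dolichol_var_growth = 0.5,
                             accel_offsets = c(WND = 0, ASD = 6,
                                               SZ = 6, DS = 8),
                             ethnicity_levels = c("Caucasian", "HanChinese",
                                                  "Other"),
                             ethnicity_fractions = c(0.5, 0.3, 0.2),
                             ethnicity_effect = 1,
                             n_ethnicity_lipids = 10L,
                             missing_rate = 0.0198,
                             noise_sd = 1,
                             age_jitter_sd = 2,
                             seed = 1L) {
  if (n_samples < 1 || n_lipids < 1 || n_dolichols < 1)
    stop("counts must be positive")
  if (n_dolichols > n_lipids) stop("n_dolichols must be <= n_lipids")
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("group_fractions must sum to 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (abs(sum(ethnicity_fractions) - 1) > 1e-8)
    stop("ethnicity_fractions must sum to 1")
  if (age_range[1] >= age_range[2]) stop("age_range must be increasing")
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 group_fractions = group_fractions,
                 n_lipids = as.integer(n_lipids),
                 n_dolichols = as.integer(n_dolichols),
                 dolichol_slope = dolichol_slope,
                 dolichol_var_growth = dolichol_var_growth,
                 accel_offsets = accel_offsets,
                 ethnicity_levels = ethnicity_levels,
                 ethnicity_fractions = ethnicity_fractions,
                 ethnicity_effect = ethnicity_effect,
                 n_ethnicity_lipids = as.integer(n_ethnicity_lipids),
                 missing_rate = missing_rate, noise_sd = noise_sd,
                 age_jitter_sd = age_jitter_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministically allocate n items to groups matching fractions
.allocate_counts <- function(n, fractions) {
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_part <- fractions * n - counts
    extra <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Generate a synthetic lipidomic cohort
#'
#' Samples chronological ages uniformly over `age_range`; each sample's
#' biological age is chronological age + its group's acceleration offset +
#' Gaussian jitter.  Dolichol features increase linearly with biological age
#' with heteroscedastic noise (sd growing linearly per decade); non-dolichol
#' features are a mix of flat, weakly age-related and ethnicity-shifted
#' lipids.  All generating parameters are retained in `ground_truth`.
#'
#' @param config a [synthetic_config()].
#' @return a [lipidomics_dataset()] with `ground_truth` populated.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  local_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_lipids
    nd <- config$n_dolichols

    age <- runif(n, config$age_range[1], config$age_range[2])
    counts <- .allocate_counts(n, config$group_fractions)
    diagnosis <- sample(rep(names(config$group_fractions), counts))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    ec <- .allocate_counts(n, config$ethnicity_fractions)
    ethnicity <- sample(rep(config$ethnicity_levels, ec))
    pmi <- round(rgamma(n, shape = 4, scale = 3.5), 1)

    offsets <- config$accel_offsets[diagnosis]
    bio_age <- age + offsets + rnorm(n, 0, config$age_jitter_sd)

    # lipid annotations
    iso <- 19 + (seq_len(nd) - 1) %% 3          # isoprene-unit count
    dol_names <- sprintf("dolichol-%d_v%d", iso,
                         ((seq_len(nd) - 1) %/% 3) + 1)
    other_names <- sprintf("lipid_%03d", seq_len(p - nd))
    lip_names <- c(dol_names, other_names)
    formula <- c(sprintf("C%dH%dO", 5 * iso, 8 * iso + 2),
                 sprintf("C%dH%dO%d", 30 + seq_len(p - nd) %% 20,
                         50 + seq_len(p - nd) %% 30,
                         2 + seq_len(p - nd) %% 6))
    lm_id <- sprintf("LMSYN%08d", seq_len(p))
    mw <- c(1314 + 68.12 * (iso - 19),
            400 + 5 * (seq_len(p - nd) %% 100) + runif(p - nd, -1, 1))
    rt <- round(runif(p, 1, 30), 2)
    lipids <- data.frame(name = lip_names, formula = formula, lm_id = lm_id,
                         molecular_weight = mw, retention_time = rt,
                         is_dolichol = c(rep(TRUE, nd), rep(FALSE, p - nd)),
                         stringsAsFactors = FALSE)

    # per-lipid generating parameters
    type <- c(rep("dolichol", nd),
              rep(c("flat", "weak_linear"), length.out = p - nd))
    n_eth <- min(config$n_ethnicity_lipids, p - nd)
    eth_flag <- c(rep(FALSE, nd), rep(FALSE, p - nd))
    if (n_eth > 0) eth_flag[nd + seq_len(n_eth)] <- TRUE
    intercept <- c(runif(nd, 20, 60), runif(p - nd, 10, 100))
    slope <- c(rep(config$dolichol_slope, nd),
               ifelse(type[-seq_len(nd)] == "weak_linear",
                      runif(p - nd, -0.05, 0.05), 0))
    sd0 <- rep(config$noise_sd, p)

    eth_score <- (ethnicity == "HanChinese") - (ethnicity == "Caucasian")

    values <- matrix(NA_real_, n, p, dimnames = list(NULL, lip_names))
    hsd <- config$noise_sd *
      (1 + config$dolichol_var_growth * pmax(bio_age - 20, 0) / 10)
    for (j in seq_len(p)) {
      mu <- intercept[j] + slope[j] * bio_age
      if (eth_flag[j]) mu <- mu + config$ethnicity_effect * eth_score
      sdj <- if (j <= nd) hsd else sd0[j]
      values[, j] <- mu + rnorm(n, 0, sdj)
    }

    samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                          reported_age = age + GESTATION_YEARS,
                          standardized_age = age, sex = sex,
                          ethnicity = ethnicity, pmi = pmi,
                          diagnosis = diagnosis, stringsAsFactors = FALSE)
    gt <- list(samples = data.frame(sample_id = samples$sample_id,
                                    biological_age = bio_age,
                                    accel_offset = unname(offsets)),
               lipids = data.frame(name = lip_names, type = type,
                                   intercept = intercept, slope = slope,
                                   noise_sd = sd0,
                                   var_growth = ifelse(seq_len(p) <= nd,
                                                       config$dolichol_var_growth, 0),
                                   ethnicity_shifted = eth_flag,
                                   stringsAsFactors = FALSE))
    ds <- lipidomics_dataset(values, samples, lipids, ground_truth = gt)
    if (config$missing_rate > 0)
      ds <- inject_missingness(ds, config$missing_rate,
                               seed = derive_seed(config$seed, 1L))
    ds
  })
}

#' Inject missing values completely at random
#'
#' @param dataset a [lipidomics_dataset()].
#' @param rate proportion of cells to set missing, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the dataset with cells masked; metadata untouched.
#' @export
inject_missingness <- function(dataset, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(dataset)
  local_seed(seed, {
    mask <- matrix(runif(length(dataset$values)) < rate,
                   nrow = nrow(dataset$values))
    dataset$values[mask] <- NA_real_
  })
  dataset
}
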