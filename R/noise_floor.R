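#' Generator-implied error floor for clock evaluation
#'
#' The best achievable median absolute error (years) for any age predictor
#' on a synthetic cohort, derived from the generating model: chronological
#' age is obscured by the individual biological-age jitter (sd
#' `age_jitter_sd`) and by measurement noise on the dolichol panel.  Each
#' dolichol carries age information with noise sd
#' `noise_sd * (1 + dolichol_var_growth * (age - 20)/10)` on the
#' concentration scale, i.e. `sd/slope` years; combining the
#' `n_dolichols` independent readouts at the cohort's mean age gives the
#' measurement variance.  For a Gaussian error of sd `s`, the median
#' absolute error is `qnorm(0.75) * s`.
#'
#' @param config a [synthetic_config()] with a nonzero `dolichol_slope`.
#' @return the floor median absolute error in years.
#' @export
clock_noise_floor <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$dolichol_slope == 0)
    stop("no age signal: dolichol_slope is 0")
  mean_age <- mean(config$age_range)
  sd_eps <- config$noise_sd *
    (1 + config$dolichol_var_growth * (mean_age - 20) / 10)
  var_meas <- sd_eps^2 / (config$n_dolichols * config$dolichol_slope^2)
  stats::qnorm(0.75) * sqrt(config$age_jitter_sd^2 + var_meas)
}
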