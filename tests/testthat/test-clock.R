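test_that("elastic net handles the penalized null fit exactly", {
  X <- matrix(rnorm(20), 10, 2)
  fit <- fit_elastic_net(X, rep(5, 10), mixing = 0.5, strength = 1)
  expect_identical(unname(fit$beta), c(0, 0))
  expect_identical(fit$intercept, 5)
})

test_that("elastic net at vanishing strength matches normal-equations OLS", {
  set.seed(11)
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  fit <- fit_elastic_net(X, y, mixing = 0.5, strength = 1e-8)
  Xd <- cbind(1, X)
  ols <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(unname(fit$beta), unname(ols[2:3]), tolerance = 1e-6)
  expect_equal(fit$intercept, ols[1], tolerance = 1e-6)

  # single-column design (closed form) against OLS too
  f1 <- fit_elastic_net(X[, 1, drop = FALSE], y, strength = 1e-10)
  o1 <- coef(lm(y ~ X[, 1]))
  expect_equal(unname(f1$beta), unname(o1[2]), tolerance = 1e-6)
})

test_that("ridge splits coefficients equally across duplicated predictors", {
  set.seed(12)
  x <- rnorm(30)
  X <- cbind(a = x, b = x)
  y <- 2 * x + rnorm(30, 0, 0.1)
  fit <- fit_elastic_net(X, y, mixing = 0, strength = 0.5)
  expect_equal(fit$beta[["a"]], fit$beta[["b"]], tolerance = 1e-6)
  expect_gt(fit$beta[["a"]], 0)
})

test_that("correlation-matrix PCA has the analytic spectrum", {
  x <- rnorm(20)
  X <- cbind(x, 3 * x + 1)           # exact line: eigenvalues (2, 0)
  expect_warning(p <- fit_pca(X), regexp = NA)
  expect_equal(p$lambda, c(2, 0), tolerance = 1e-12)

  set.seed(13)
  X2 <- matrix(rnorm(40), 10, 4)
  p2 <- fit_pca(X2)
  expect_equal(sum(p2$lambda), 4, tolerance = 1e-10)   # trace conservation
  expect_equal(crossprod(p2$Q), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)

  # brute-force eigendecomposition oracle (up to sign)
  e <- eigen(cor(X2), symmetric = TRUE)
  expect_equal(p2$lambda, e$values, tolerance = 1e-8)
  for (k in 1:4)
    expect_equal(abs(p2$Q[, k]), abs(e$vectors[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("zero-variance features are dropped from PCA with a warning", {
  X <- cbind(rnorm(10), rep(2, 10), rnorm(10))
  colnames(X) <- c("a", "const", "b")
  expect_warning(p <- fit_pca(X), "const")
  expect_equal(rownames(p$Q), c("a", "b"))
})

test_that("stratified resampling preserves every stratum's count", {
  strata <- rep(c("a", "b", "c"), c(5, 3, 9))
  idx <- stratified_indices(strata, n_iter = 25, seed = 4)
  for (it in idx) {
    expect_length(it, 17)
    expect_equal(as.vector(table(strata[it])), c(5, 3, 9))
  }
  expect_identical(idx, stratified_indices(strata, 25, seed = 4))
  expect_error(stratified_indices(strata, 0, seed = 1), "n_iter")
})

test_that("the bootstrap is deterministic and strata are preserved", {
  ds <- generate_cohort(small_config(n_samples = 80L, seed = 31L))
  b1 <- run_bootstrap(ds, n_iter = 3, seed = 17)
  b2 <- run_bootstrap(ds, n_iter = 3, seed = 17)
  expect_equal(b1, b2)
  expect_length(b1$mae, 3)
  # singleton strata are always redrawn, keeping the fraction below the
  # single-stratum limit (1 - 1/n)^n
  expect_true(all(b1$oob_fraction > 0 & b1$oob_fraction < 0.45))
})

test_that("median-model selection follows the lower-middle rule", {
  fake <- function(maes) structure(
    list(mae = maes, models = lapply(seq_along(maes), function(i)
      list(id = i))), class = "clock_bootstrap")
  expect_equal(select_median_model(fake(c(5, 9, 20)))$id, 2)
  expect_equal(select_median_model(fake(c(5, 9, 11, 20)))$id, 2)
  expect_equal(select_median_model(fake(c(20, 9, 5, 11)))$id, 2)
  # ties at the median resolve to the earliest iteration
  expect_equal(select_median_model(fake(c(9, 9, 9)))$id, 1)
  # invalid iterations are excluded
  expect_equal(select_median_model(fake(c(NA, 5, 9, 20)))$id, 3)
  expect_error(select_median_model(fake(c(NA_real_, NA_real_))),
               "no valid")
})

test_that("selected model's error sits inside the bootstrap IQR", {
  ds <- generate_cohort(synthetic_config(n_samples = 150L, seed = 33L))
  b <- run_bootstrap(ds, n_iter = 30, seed = 5)
  m <- select_median_model(b)
  q <- quantile(b$mae, c(0.25, 0.75), na.rm = TRUE)
  expect_gte(m$oob_mae, q[[1]])
  expect_lte(m$oob_mae, q[[2]])
})

test_that("prediction is reproducible and fails on unseen factor levels", {
  ds <- generate_cohort(small_config(n_samples = 70L, seed = 34L))
  wnd <- subset_dataset(ds, samples = ds$samples$diagnosis == "WND")
  m <- lipid_clock(wnd)
  pred <- predict(m, wnd)
  expect_equal(median(abs(pred - wnd$samples$standardized_age)),
               m$train_mae)
  expect_equal(unname(pred), m$train_fitted)

  alien <- wnd
  alien$samples$ethnicity[1] <- "Klingon"
  expect_error(predict(m, alien), "Klingon")
})

test_that("an all-zero coefficient model predicts its intercept", {
  ds <- generate_cohort(small_config(n_samples = 50L, seed = 35L))
  m <- lipid_clock(ds, strength = 1e6)   # penalty crushes every coefficient
  expect_true(all(m$beta == 0))
  pred <- predict(m, ds)
  expect_equal(unname(pred), rep(m$intercept, nrow(ds$values)))
})

test_that("a noiseless single dolichol gives near-perfect age prediction", {
  cfg <- synthetic_config(n_samples = 200L, n_lipids = 1L, n_dolichols = 1L,
                          dolichol_slope = 0.5, noise_sd = 0,
                          dolichol_var_growth = 0, age_jitter_sd = 0,
                          accel_offsets = c(WND = 0, ASD = 0, SZ = 0, DS = 0),
                          missing_rate = 0, seed = 36L)
  ds <- generate_cohort(cfg)
  m <- lipid_clock(ds, covariates = NULL, strength = 1e-8)
  pred <- predict(m, ds)
  line <- coef(lm(pred ~ ds$samples$standardized_age))
  expect_lt(abs(line[[2]] - 1), 1e-3)
  expect_lt(median(abs(pred - ds$samples$standardized_age)), 0.5)
})

test_that("age-acceleration residuals behave under translation", {
  set.seed(14)
  age <- runif(120, 20, 80)
  groups <- rep(c("WND", "ASD"), c(90, 30))
  pred <- 2 + 0.9 * age
  rep0 <- compute_age_acceleration(pred, age, groups)
  expect_equal(unname(rep0$delta[groups == "WND"]), rep(0, 90),
               tolerance = 1e-10)

  # disorder predictions shifted +5 years: median residual difference = 5
  pred5 <- pred + 5 * (groups == "ASD")
  rep5 <- compute_age_acceleration(pred5, age, groups)
  expect_equal(median(rep5$delta[groups == "ASD"]) -
                 median(rep5$delta[groups == "WND"]), 5, tolerance = 1e-10)
  expect_lt(rep5$tests$p_adjusted[rep5$tests$group == "ASD"], 0.05)

  # adding a constant to every prediction is absorbed by the line
  repc <- compute_age_acceleration(pred5 + 12, age, groups)
  expect_equal(repc$delta, rep5$delta, tolerance = 1e-10)

  expect_error(compute_age_acceleration(pred[1:3], rep(50, 3),
                                        rep("WND", 3)), "constant")
})

test_that("the stored regression line matches an external slope fit", {
  ds <- generate_cohort(small_config(n_samples = 90L, seed = 37L))
  wnd <- subset_dataset(ds, samples = ds$samples$diagnosis == "WND")
  m <- lipid_clock(wnd)
  pred <- predict(m, ds)
  acc <- compute_age_acceleration(pred, ds$samples$standardized_age,
                                  ds$samples$diagnosis)
  keep <- ds$samples$diagnosis == "WND"
  sc <- slope_comparison(pred[keep], ds$samples$standardized_age[keep],
                         rep("WND", sum(keep)))
  expect_equal(unname(acc$line["slope"]), sc$reference_slope,
               tolerance = 1e-10)
  expect_equal(unname(acc$line["intercept"]), sc$reference_intercept,
               tolerance = 1e-10)
})
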