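test_that("age standardization subtracts the gestational period exactly", {
  expect_identical(standardize_age(0.767), 0)
  expect_equal(standardize_age(24), 23.233)
  expect_equal(standardize_age(80.767), 80)
  # inverse property
  x <- c(0, 0.5, 20, 63.2, 99)
  expect_equal(standardize_age(x + 0.767), x)
  expect_error(standardize_age(-1), ">= 0")
})

test_that("age filtering keeps both endpoints and allows empty results", {
  ds <- make_tiny_dataset(matrix(rnorm(10), 5, 2),
                          ages = c(10, 20, 50, 80, 90))
  kept <- filter_age_range(ds, 20, 80)
  expect_equal(kept$samples$standardized_age, c(20, 50, 80))
  expect_equal(nrow(kept$values), 3)
  empty <- filter_age_range(ds, 30, 30.0001)
  expect_equal(nrow(empty$values), 0)
  expect_error(filter_age_range(ds, 50, 50), "lo must be < hi")
})

test_that("uniform ages survive the 20-80 filter at the expected rate", {
  set.seed(1)
  ages <- runif(1000, 0, 100)
  ds <- make_tiny_dataset(matrix(rnorm(2000), 1000, 2), ages = ages)
  frac <- nrow(filter_age_range(ds, 20, 80)$values) / 1000
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 1000))
})

test_that("duplicate annotations resolve by relative mass deviation", {
  ds <- make_tiny_dataset(matrix(rnorm(20), 5, 4))
  expect_identical(resolve_duplicate_annotations(ds)$lipids, ds$lipids)

  # two features share an LM ID; 2 ppm beats 40 ppm
  m <- formula_mass("C20H40O2")
  lip <- data.frame(
    name = c("feat_b", "feat_a", "feat_c"),
    formula = c("C20H40O2", "C20H40O2x", "C30H50O"),
    lm_id = c("LMGL0001", "LMGL0001", "LMGL0002"),
    molecular_weight = c(m * (1 + 2e-6), m * (1 + 40e-6), 500),
    retention_time = 1:3, is_dolichol = FALSE,
    stringsAsFactors = FALSE)
  lip$formula[2] <- "C20H40O2"  # same formula, worse mass match
  ds2 <- make_tiny_dataset(matrix(rnorm(15), 5, 3), lipids = lip)
  out <- resolve_duplicate_annotations(ds2)
  expect_setequal(out$lipids$name, c("feat_b", "feat_c"))

  # equal deviations: lexicographically first name wins
  lip3 <- data.frame(
    name = c("zeta", "alpha", "mid"),
    formula = "C20H40O2", lm_id = NA_character_,
    molecular_weight = m, retention_time = 1:3, is_dolichol = FALSE,
    stringsAsFactors = FALSE)
  ds3 <- make_tiny_dataset(matrix(rnorm(15), 5, 3), lipids = lip3)
  expect_equal(resolve_duplicate_annotations(ds3)$lipids$name, "alpha")

  # missing molecular weight loses the tie, with a warning
  lip4 <- lip3
  lip4$molecular_weight <- c(m, NA, m)
  ds4 <- make_tiny_dataset(matrix(rnorm(15), 5, 3), lipids = lip4)
  expect_warning(out4 <- resolve_duplicate_annotations(ds4),
                 "molecular weight")
  expect_equal(out4$lipids$name, "mid")
})

test_that("formula masses follow the atomic mass table", {
  expect_equal(formula_mass("H2O"), 2 * 1.00782503207 + 15.99491461956)
  expect_equal(formula_mass("C2"), 24)
  expect_true(is.na(formula_mass("Xx9")))
})

test_that("symmetric point sets yield no outliers", {
  sq <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  ds <- make_tiny_dataset(cbind(sq, rnorm(4) * 0), ages = c(30, 40, 50, 60))
  rep <- detect_outliers(ds, n_components = 2)
  expect_length(rep$flagged, 0)
})

test_that("a gross outlier is flagged, and only it", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40), 20, 2), c(100, 100))
  ds <- make_tiny_dataset(x, ages = seq(20, 80, length.out = 21))
  rep <- detect_outliers(ds, n_components = 2)
  expect_equal(rep$flagged, ds$samples$sample_id[21])

  # brute-force oracle: mean Euclidean distance on centred raw data
  xc <- scale(x, scale = FALSE)
  d <- as.matrix(dist(xc))
  md <- rowSums(d) / 20
  expect_equal(unname(rep$mean_distance), unname(md), tolerance = 1e-8)
})

test_that("outlier decisions survive duplication and rotation", {
  set.seed(6)
  x <- rbind(matrix(rnorm(30), 15, 2), c(50, -50))
  ds <- make_tiny_dataset(x, ages = seq(20, 80, length.out = 16))
  base <- detect_outliers(ds, n_components = 2)

  dup <- make_tiny_dataset(rbind(x, x), ages = rep(seq(20, 80,
                                                       length.out = 16), 2))
  rep2 <- detect_outliers(dup, n_components = 2)
  flag2a <- dup$samples$sample_id[1:16] %in% rep2$flagged
  flag2b <- dup$samples$sample_id[17:32] %in% rep2$flagged
  expect_identical(flag2a, flag2b)

  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rot <- make_tiny_dataset(x %*% R, ages = seq(20, 80, length.out = 16))
  rep3 <- detect_outliers(rot, n_components = 2)
  expect_equal(unname(rep3$mean_distance), unname(base$mean_distance),
               tolerance = 1e-8)
  expect_identical(rep3$flagged, base$flagged)
})

test_that("KNN imputation matches the hand-worked example", {
  x <- matrix(c(1, NA, 1, 10, 1, 12), 3, 2, byrow = TRUE)
  out <- lipoclock:::.knn_impute(x, x, k = 2)
  expect_equal(out[1, 2], 11)        # equidistant neighbours average
  expect_equal(out[-1, ], x[-1, ])   # observed values untouched
})

test_that("imputation is the identity on complete data and errors on an
          all-missing lipid", {
  x <- matrix(rnorm(20), 5, 4)
  expect_identical(lipoclock:::.knn_impute(x, x, 3), x)
  xm <- x; xm[, 2] <- NA
  ds <- make_tiny_dataset(xm)
  expect_error(fit_transform(ds, k = 2), "lip02")
})

test_that("fitted transform standardizes training lipids exactly", {
  set.seed(8)
  x <- matrix(rexp(200, 0.2), 40, 5)
  x[sample(200, 6)] <- NA
  ds <- make_tiny_dataset(x)
  st <- fit_transform(ds, k = 5)
  z <- apply_transform(st, ds)$values
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-9)
})

test_that("apply_transform treats each sample independently", {
  set.seed(9)
  xtr <- matrix(rnorm(60, 10, 3), 12, 5)
  ds_tr <- make_tiny_dataset(xtr)
  st <- fit_transform(ds_tr, k = 3)
  xte <- matrix(rnorm(20, 10, 3), 4, 5)
  xte[2, 3] <- NA
  ds_te <- make_tiny_dataset(xte)
  batch <- apply_transform(st, ds_te)$values
  for (i in 1:4) {
    solo <- apply_transform(st, subset_dataset(ds_te, samples = i))$values
    expect_equal(unname(solo[1, ]), unname(batch[i, ]))
  }
})

test_that("Yeo-Johnson behaves at its analytic limits", {
  x <- c(-3, -0.5, 0, 0.2, 1, 7)
  expect_identical(yeo_johnson(x, 1), x)           # lambda = 1 identity
  expect_equal(yeo_johnson(c(0.5, 3), 0), log1p(c(0.5, 3)))
  expect_equal(yeo_johnson(-2, 2), -log1p(2))
  # monotone for several lambdas
  for (l in c(-1, 0, 0.5, 1, 2.5))
    expect_true(all(diff(yeo_johnson(sort(x), l)) > 0))
})

test_that("the lambda MLE agrees with an independent implementation", {
  skip_if_not_installed("car")
  set.seed(10)
  x <- rexp(300, 0.5)
  ours <- yj_lambda(x)
  theirs <- car::powerTransform(x, family = "yjPower")$lambda
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})
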