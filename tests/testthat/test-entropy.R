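test_that("binarization is strict at the threshold boundary", {
  ref <- identity_reference(c("a", "b", "c"), threshold = 2)
  vals <- matrix(c(2, 0, 5,
                   -2, 2.0000001, -5), 2, 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  ds <- make_tiny_dataset(vals, ages = c(30, 35))
  D <- binarize(ref, ds)
  expect_identical(unname(D[1, ]), c(0L, 0L, 1L))  # exactly 2 sd is not a deviation
  expect_identical(unname(D[2, ]), c(0L, 1L, 1L))
})

test_that("an infinite threshold silences the deviation matrix", {
  ref <- identity_reference(c("a", "b"), threshold = Inf)
  ds <- make_tiny_dataset(matrix(rnorm(20, 0, 50), 10, 2,
                                 dimnames = list(NULL, c("a", "b"))))
  expect_true(all(binarize(ref, ds) == 0L))
})

test_that("missing cells never count as deviations", {
  ref <- identity_reference(c("a", "b"))
  vals <- matrix(c(NA, 9, 9, NA), 2, 2,
                 dimnames = list(NULL, c("a", "b")))
  ds <- make_tiny_dataset(vals, ages = c(30, 35))
  expect_message(D <- binarize(ref, ds), "missing")
  expect_identical(unname(D), matrix(c(0L, 1L, 1L, 0L), 2, 2))
})

test_that("the reference window is restricted to healthy samples", {
  set.seed(15)
  vals <- matrix(rnorm(400, 50, 5), 100, 4)
  diag <- rep(c("WND", "SZ"), c(80, 20))
  ds <- make_tiny_dataset(vals, ages = rep(seq(21, 39, length.out = 25), 4),
                          diagnosis = diag)
  expect_message(ref <- fit_reference(ds), "excluded 20")
  expect_equal(ref$n_reference, 80)
  expect_error(fit_reference(subset_dataset(ds, samples = integer(0))),
               "empty")
})

test_that("the reference window calibrates near the two-sigma tail mass", {
  set.seed(16)
  vals <- matrix(rnorm(200 * 30, 100, 10), 200, 30)
  ds <- make_tiny_dataset(vals, ages = runif(200, 20, 40))
  ref <- fit_reference(ds)
  D <- binarize(ref, ds)
  rate <- mean(colMeans(D))
  expect_lt(abs(rate - 2 * pnorm(-2)), 0.015)
})

test_that("dolichol deviation frequency rises across age bins", {
  ds <- generate_cohort(synthetic_config(n_samples = 400L, seed = 41L))
  ref <- fit_reference(ds)
  D <- binarize(ref, ds)
  dol <- ds$lipids$is_dolichol
  ge <- group_entropy(D, ds$samples$standardized_age)
  freq <- rowMeans(ge$frequency[, dol])
  expect_lt(freq[["[20,30)"]], freq[["[40,50)"]])
  expect_lt(freq[["[40,50)"]], freq[["[60,70)"]])
  expect_gt(cor(seq_along(freq), freq, method = "spearman"), 0.9)
})

test_that("group entropy evaluates the binary entropy exactly", {
  D <- matrix(c(1, 1, 0, 0,   # f = 0.5 -> 1 bit
                1, 1, 1, 1,   # f = 1   -> 0
                0, 0, 0, 0,   # f = 0   -> 0
                1, 0, 0, 0),  # f = 0.25 -> 0.8113 bits
              4, 4, dimnames = list(NULL, c("w", "x", "y", "z")))
  ge <- group_entropy(D, ages = rep(25, 4), bin_width = 10)
  h <- ge$per_lipid_h[1, ]
  expect_equal(h[["w"]], 1)
  expect_equal(h[["x"]], 0)
  expect_equal(h[["y"]], 0)
  expect_equal(h[["z"]], -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_equal(ge$summary$H_group,
               mean(c(1, 0, 0, 0.8112781)), tolerance = 1e-6)
  expect_true(all(ge$per_lipid_h <= 1))
})

test_that("individual entropy covers its degenerate cases", {
  # 8 healthy references in one bin: lipid A deviates once (f = 1/8),
  # lipid B four times (f = 1/2)
  D <- rbind(matrix(c(1, 0, 0, 0, 0, 0, 0, 0,
                      1, 1, 1, 1, 0, 0, 0, 0), 8, 2),
             c(0, 0),    # no deviations -> 0
             c(1, 0),    # single deviation -> 0
             c(1, 1))    # two deviations -> depends on weights
  colnames(D) <- c("A", "B")
  rownames(D) <- sprintf("S%02d", 1:11)
  ages <- rep(25, 11)
  diagnosis <- c(rep("WND", 8), rep("ASD", 3))
  H <- individual_entropy(D, ages, diagnosis)
  expect_equal(H[["S09"]], 0)
  expect_equal(H[["S10"]], 0)
  # weights w = (-log2(1/8), -log2(1/2)) = (3, 1); q = (3/4, 1/4)
  expect_equal(H[["S11"]], -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_lte(H[["S11"]], log2(2))

  # equal frequencies give the uniform two-outcome bit
  D2 <- rbind(matrix(c(1, 0, 0, 0,
                       1, 0, 0, 0), 4, 2), c(1, 1))
  colnames(D2) <- c("A", "B")
  H2 <- individual_entropy(D2, rep(30, 5), c(rep("WND", 4), "SZ"))
  expect_equal(H2[[5]], 1)

  # surprisal-sum mode returns the total surprisal instead
  Hs <- individual_entropy(D, ages, diagnosis, mode = "surprisal-sum")
  expect_equal(Hs[["S11"]], 3 + 1)
  expect_equal(Hs[["S09"]], 0)
})

test_that("top contributors pick the rarest deviating lipid", {
  D <- rbind(matrix(c(1, 0, 0, 0, 0, 0, 0, 0,
                      1, 1, 1, 1, 0, 0, 0, 0), 8, 2),
             c(1, 1), c(0, 1), c(0, 0))
  colnames(D) <- c("A", "B")
  top <- entropy_contributors(D, rep(25, 11), c(rep("WND", 8), rep("DS", 3)))
  expect_equal(unname(top[9:11]), c("A", "B", NA))
})

test_that("entropy is invariant to lipid order and monotone in threshold", {
  ds <- generate_cohort(small_config(n_samples = 100L, seed = 43L))
  ref <- fit_reference(ds)
  D <- binarize(ref, ds)
  perm <- sample(ncol(D))
  ref_p <- lipoclock:::.subset_reference(ref, colnames(D)[perm])
  Dp <- binarize(ref_p, ds)
  expect_identical(Dp, D[, perm])
  H1 <- individual_entropy(D, ds$samples$standardized_age,
                           ds$samples$diagnosis)
  H2 <- individual_entropy(Dp, ds$samples$standardized_age,
                           ds$samples$diagnosis)
  expect_equal(H1, H2)

  ref3 <- fit_reference(ds, threshold = 3)
  expect_true(all(binarize(ref3, ds) <= D))
  expect_true(all(H1 <= log2(pmax(rowSums(D), 2))))
})

test_that("dolichol entropy reduces to individual entropy on a pure panel", {
  cfg <- small_config(n_samples = 80L, seed = 44L)
  cfg$n_dolichols <- cfg$n_lipids  # every lipid is a dolichol
  ds <- generate_cohort(cfg)
  ref <- fit_reference(ds)
  D <- binarize(ref, ds)
  expect_equal(dolichol_entropy(ds, ref),
               individual_entropy(D, ds$samples$standardized_age,
                                  ds$samples$diagnosis))

  one_dol <- subset_dataset(ds, lipids = 1)
  expect_error(dolichol_entropy(one_dol, ref), "at least 2")
})

test_that("group entropy is flat when every sample follows the reference
          distribution", {
  pvals <- numeric(25)
  for (s in 1:25) {
    set.seed(600 + s)
    vals <- matrix(rnorm(150 * 20, 80, 8), 150, 20)
    ds <- make_tiny_dataset(vals, ages = runif(150, 20, 80))
    ref <- fit_reference(ds)
    D <- binarize(ref, ds)
    ge <- group_entropy(D, ds$samples$standardized_age)
    ct <- suppressWarnings(cor.test(seq_len(nrow(ge$summary)),
                                    ge$summary$H_group,
                                    method = "spearman"))
    pvals[s] <- ct$p.value
  }
  expect_lte(mean(pvals < 0.05), 0.2)
})
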