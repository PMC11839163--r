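test_that("fisher exact matches closed cases and full enumeration", {
  expect_equal(fisher_exact(contingency_2x2(5, 5, 5, 5)), 1.0)
  expect_equal(fisher_exact(contingency_2x2(2, 0, 0, 2)), 1 / 3,
               tolerance = 1e-12)
  # transposition symmetry
  m <- matrix(c(7, 3, 2, 9), 2)
  expect_equal(fisher_exact(m), fisher_exact(t(m)))
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")

  withr::local_seed(17)
  for (k in 1:200) {
    n <- sample(4:200, 1)
    a <- sample(0:n, 1)
    b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1)
    d <- n - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_exact(contingency_2x2(a, b, c, d)),
                 oracle_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("koopman interval matches the aggregate-counts ratio and the grid oracle", {
  # aggregate turn/miss counts: GT 206/112, ST 158/72
  res <- koopman_rr_ci(contingency_2x2(206, 112, 158, 72))
  expect_equal(res$rr, (206 / 318) / (158 / 230), tolerance = 1e-12)
  expect_equal(res$rr, 0.943, tolerance = 1e-3)
  expect_true(res$ci_low < res$rr && res$rr < res$ci_high)

  balanced <- koopman_rr_ci(contingency_2x2(10, 10, 10, 10))
  expect_equal(balanced$rr, 1.0)
  expect_true(balanced$ci_low < 1 && balanced$ci_high > 1)

  tables <- list(c(206, 112, 158, 72), c(30, 10, 18, 22), c(5, 15, 12, 8),
                 c(40, 2, 35, 6), c(9, 1, 3, 7))
  for (tb in tables) {
    got <- koopman_rr_ci(do.call(contingency_2x2, as.list(tb)))
    want <- oracle_koopman_ci(tb[1], tb[1] + tb[2], tb[3], tb[3] + tb[4])
    expect_equal(got$ci_low, want[1], tolerance = 1e-3)
    expect_equal(got$ci_high, want[2], tolerance = 1e-3)
    # reciprocal table inverts the estimate and the interval
    rec <- koopman_rr_ci(contingency_2x2(tb[3], tb[4], tb[1], tb[2]))
    expect_equal(rec$rr, 1 / got$rr, tolerance = 1e-9)
    expect_equal(rec$ci_low, 1 / got$ci_high, tolerance = 1e-6)
    expect_equal(rec$ci_high, 1 / got$ci_low, tolerance = 1e-6)
  }

  # zero cells yield flagged one-sided results
  z <- koopman_rr_ci(contingency_2x2(12, 3, 0, 10))
  expect_true(is.infinite(z$rr))
  expect_true(z$one_sided)
  expect_true(is.finite(z$ci_low))
  z2 <- koopman_rr_ci(contingency_2x2(0, 10, 12, 3))
  expect_equal(z2$rr, 0)
  expect_equal(z2$ci_low, 0)
  expect_true(is.finite(z2$ci_high))
})

test_that("pearson chi-square matches hand computations and is permutation invariant", {
  expect_equal(pearson_chi_square(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  r <- pearson_chi_square(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(r$statistic, 20.0)
  expect_equal(r$df, 1)
  r2 <- pearson_chi_square(matrix(c(60, 30, 10, 20, 50, 30), 2, byrow = TRUE))
  expect_equal(r2$statistic, 35.0)
  expect_equal(r2$df, 2)
  m <- matrix(c(60, 30, 10, 20, 50, 30), 2, byrow = TRUE)
  perm <- m[c(2, 1), c(3, 1, 2)]
  expect_equal(pearson_chi_square(perm)$statistic, 35.0)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

sim_features <- function(n_per, gt_shift = 0, seed = 1) {
  withr::with_seed(seed, {
    ph <- rep(c("GT", "ST"), each = n_per)
    npk <- sample(1:3, 2 * n_per, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    amp <- rlnorm(2 * n_per, log(4), 0.5) + ifelse(ph == "GT", gt_shift, 0)
    turn_p <- plogis(0.2 * (amp - 4))
    data.frame(phenotype = ph, n_peaks = npk, max_peak = amp,
               outcome = ifelse(runif(2 * n_per) < turn_p, "turn", "miss"))
  })
}

test_that("threshold sweep counts are monotone and label swap inverts the ratio", {
  f <- sim_features(400, gt_shift = 1, seed = 5)
  sw <- threshold_sweep(f, thresholds = c(1, 2, 3, 4, 6))
  for (cls in unique(sw$peak_class)) {
    n <- sw$n[sw$peak_class == cls]
    expect_true(all(diff(n) <= 0))
  }
  # swapping phenotype labels inverts every rr and preserves every p
  f_sw <- f
  f_sw$phenotype <- ifelse(f$phenotype == "GT", "ST", "GT")
  sw2 <- threshold_sweep(f_sw, thresholds = c(1, 2, 3, 4, 6))
  ok <- is.finite(sw$rr) & sw$rr > 0
  expect_equal(sw2$rr[ok], 1 / sw$rr[ok], tolerance = 1e-12)
  expect_equal(sw2$p_fisher[ok], sw$p_fisher[ok], tolerance = 1e-9)

  # any cell below 10 excludes the condition
  expect_true(all(!sw$included[pmin(sw$gt_turns, sw$gt_misses,
                                    sw$st_turns, sw$st_misses) < 10]))
  small <- threshold_sweep(sim_features(8, seed = 2), thresholds = 1)
  expect_true(all(!small$included))
  expect_error(threshold_sweep(sim_features(10)[0, ]), "non-empty")
})

test_that("identically distributed phenotypes give null relative probabilities", {
  f <- sim_features(800, gt_shift = 0, seed = 11)
  sw <- threshold_sweep(f, thresholds = c(1, 2, 3), peak_classes = "any")
  expect_true(all(abs(log(sw$rr)) < 0.25))
  expect_true(all(sw$ci_low < 1 & sw$ci_high > 1 | sw$p_fisher < 0.05 |
                    abs(log(sw$rr)) < 0.25))
})
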