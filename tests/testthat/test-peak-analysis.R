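bl <- list(mean = 0, sd = 1)

test_that("peak detector reproduces the worked window examples", {
  expect_equal(nrow(detect_peaks(c(0, 0, 0, 0, 0), bl)), 0)

  p1 <- detect_peaks(c(0, 0.5, 4.0, 0.5, 0), bl)
  expect_equal(p1$concentration, 4.0)
  expect_equal(p1$rule_used, "prominence")
  expect_equal(p1$apex_time_rel, 0.4)

  # inner troughs of 0.5/0.7 are not 1 SD drops: the highest point of the
  # elevation is the single peak
  p2 <- detect_peaks(c(0, 4.0, 3.5, 4.2, 0.2), bl)
  expect_equal(p2$concentration, 4.2)
  expect_equal(nrow(p2), 1)

  p3 <- detect_peaks(c(0, 4.0, 0.5, 5.0, 0), bl)
  expect_equal(p3$concentration, c(4.0, 5.0))
  expect_equal(peak_features(p3)$max_peak, 5.0)

  # sustained elevation within 1 SD, not bordered by 1 SD drops on the
  # inside: rescued once via the adjacent-run rule
  p4 <- detect_peaks(c(0, 5.0, 2.9, 3.5, 3.4, 3.5, 2.9, 0), bl)
  expect_equal(p4$concentration, c(5.0, 3.5))
  expect_equal(p4$rule_used, c("prominence", "adjacent_run"))
  expect_equal(p4$index[2], 4) # earliest of the tied run maxima

  expect_error(detect_peaks(numeric(0), bl), "empty")
  expect_error(detect_peaks(c(0, 4), list(mean = 0, sd = 0)), "sd")
})

test_that("peak detector agrees exactly with the brute-force oracle", {
  withr::local_seed(42)
  mismatches <- 0
  for (k in 1:1200) {
    v <- random_window(n = 10, sd = 1)
    got <- detect_peaks(v, bl)$index
    want <- oracle_detect_peaks(v, 0, 1)
    if (!identical(as.integer(got), as.integer(want))) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("peak set is invariant to a common sub-threshold offset", {
  withr::local_seed(7)
  for (k in 1:50) {
    v <- random_window(12, 1)
    off <- runif(1, -2, 2)
    a <- detect_peaks(v, bl)
    b <- detect_peaks(v + off, list(mean = off, sd = 1))
    expect_identical(a$index, b$index)
    expect_identical(a$rule_used, b$rule_used)
  }
})

pulse_apex_time_for_test <- function(cfg) {
  cfg$pulse_rise * cfg$pulse_decay / (cfg$pulse_decay - cfg$pulse_rise) *
    log(cfg$pulse_decay / cfg$pulse_rise)
}

test_that("noiseless single-peak amplitude is recovered within shape quantization at 5 Hz", {
  cfg <- default_generator_config()
  cfg$noise_sd <- 0
  cfg$phenotypes$GT$single_peak_prob <- 1
  cfg$phenotypes$GT$peak_amplitude_mean <- 8
  cfg$phenotypes$GT$peak_amplitude_sd <- 0
  cfg$phenotypes$GT$reward_peak_prob <- 0
  cal <- fit_calibration(gen_calibration_series(noise_sd = 0, seed = 1))
  sess <- gen_cttt_session(cfg, "GT", seed = 31)
  tr <- gen_glutamate_trace(sess, cfg, seed = 32)
  conc <- process_trace(tr, cal)
  f <- window_peak_features(extract_windows(conc, sess), kinds = "cue")
  # apexes fall between samples: the sampled maximum sits within the pulse
  # value one half-sample (0.1 s) off apex
  apx <- pulse_apex_time_for_test(cfg)
  quant <- min(transient_pulse(apx + 0.1, cfg$pulse_rise, cfg$pulse_decay),
               transient_pulse(apx - 0.1, cfg$pulse_rise, cfg$pulse_decay))
  expect_true(all(f$max_peak <= 8 + 1e-9))
  expect_true(all(f$max_peak >= 8 * quant - 1e-9))
})

test_that("features carry missing markers and classify_peak_count conserves traces", {
  empty <- peak_features(detect_peaks(c(0, 0, 0), bl))
  expect_true(is.na(empty$max_peak))
  expect_equal(empty$n_peaks, 0)
  expect_true(is.na(empty$time_to_max))

  two <- peak_features(data.frame(index = c(3, 7),
                                  apex_time_rel = c(0.4, 1.2),
                                  concentration = c(4.0, 5.0),
                                  rule_used = "prominence"))
  expect_equal(two$max_peak, 5.0)
  expect_equal(two$n_peaks, 2)
  expect_equal(two$time_to_max, 1.2)

  feats <- data.frame(
    phenotype = rep(c("GT", "ST"), each = 6),
    n_peaks = c(1, 1, 1, 2, 0, 3, 2, 2, 3, 1, 0, 4))
  tab <- classify_peak_count(feats)
  expect_equal(sum(tab), sum(feats$n_peaks >= 1))
  expect_equal(unname(tab["GT", ]), c(3, 1, 1), ignore_attr = TRUE)
  expect_equal(unname(tab["ST", ]), c(1, 2, 2), ignore_attr = TRUE)
  expect_equal(unname(attr(tab, "zero_peak")["GT"]), 1, ignore_attr = TRUE)

  all_single <- data.frame(phenotype = "GT", n_peaks = rep(1, 5))
  tab1 <- classify_peak_count(all_single)
  expect_equal(unname(tab1[1, "1"]), 5, ignore_attr = TRUE)
  expect_equal(sum(tab1[1, c("2", "3+")]), 0)
})

test_that("multi-peak prevalence matches the generator's single-peak probability", {
  # single_peak_prob 0.2: ~80% of ST cue windows carry two or three peaks
  cfg <- default_generator_config()
  cal <- fit_calibration(gen_calibration_series(noise_sd = 0, seed = 1))
  n_multi <- 0
  n_tot <- 0
  for (k in 1:30) {
    sess <- gen_cttt_session(cfg, "ST", seed = 400 + k)
    tr <- gen_glutamate_trace(sess, cfg, seed = 500 + k)
    conc <- process_trace(tr, cal)
    # a 3-s analysis window covers the full second/third-peak latency law
    w <- extract_windows(conc, sess, cue_duration = 3)
    f <- window_peak_features(w, kinds = "cue")
    n_multi <- n_multi + sum(f$n_peaks >= 2)
    n_tot <- n_tot + nrow(f)
  }
  expect_gt(n_tot, 500)
  expect_lt(abs(n_multi / n_tot - 0.8), 0.06)
})
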