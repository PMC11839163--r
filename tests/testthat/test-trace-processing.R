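noiseless_calibration <- function() {
  fit_calibration(gen_calibration_series(noise_sd = 0, seed = 1))
}

test_that("sentinel subtraction removes exactly the shared components", {
  t <- seq(0, 9.8, by = 0.2)
  shared <- 200 + 0.01 * t + 50 * (t >= 3 & t < 4) # baseline, drift, artifact
  transient <- 24 * transient_pulse(t - 6)
  tr <- new_dual_channel_trace(t, shared + transient, shared)
  net <- sentinel_subtract(tr)
  expect_equal(net, transient)
  expect_equal(sentinel_subtract(list(active = shared, sentinel = shared)),
               rep(0, length(t)))
  expect_equal(sentinel_subtract(list(active = shared + 3, sentinel = shared)),
               rep(3, length(t)))
  expect_error(sentinel_subtract(list(active = 1:5, sentinel = 1:4)), "length")
})

test_that("dopamine normalization applies only above the 0.1 pA response", {
  net <- c(6, 0, -2)
  low <- dopamine_normalize(net, 0.05)
  expect_false(low$normalized)
  expect_equal(low$values, net)
  hi <- dopamine_normalize(net, 0.5)
  expect_true(hi$normalized)
  expect_equal(hi$values, net / 0.5)
  expect_equal(hi$values[1], 12)
  unit <- dopamine_normalize(net, 1.0)
  expect_true(unit$normalized)
  expect_equal(unit$values, net)
  expect_error(dopamine_normalize(net, -0.2), "non-negative")
})

test_that("current-to-concentration conversion is linear and normalization-invariant", {
  cal <- noiseless_calibration() # slope 12 pA/uM
  expect_equal(to_concentration(24, cal)$glutamate, 2.0)
  expect_equal(to_concentration(0, cal)$glutamate, 0)
  # normalized path: net / da and slope / da cancel
  cal_da <- cal
  cal_da$da_response <- 0.5
  norm <- dopamine_normalize(24, cal_da$da_response)
  expect_equal(norm$values, 48)
  expect_equal(to_concentration(norm$values, cal_da,
                                normalized = TRUE)$glutamate, 2.0)
  # a failing calibration is refused unless overridden
  bad <- cal
  bad$passed$overall <- FALSE
  expect_error(to_concentration(24, bad), "did not pass")
  expect_equal(to_concentration(24, bad, check_passed = FALSE)$glutamate, 2.0)
})

test_that("window extraction yields the stated sample counts and baseline correction", {
  cal <- noiseless_calibration()
  t <- seq(0, 59.8, by = 0.2)
  # constant 5 uM offset plus an 8 uM transient at the cue
  cue_at <- 30
  g <- 5 + 8 * transient_pulse(t - cue_at)
  conc <- structure(list(time = t, glutamate = g, normalization_applied = FALSE),
                    class = "concentration_trace")
  events <- data.frame(trial = 1, cue_onset_s = cue_at, reward_s = 36)
  w <- extract_windows(conc, events)
  expect_equal(sum(w$window == "baseline"), 12) # floor(2.5 * 5)
  expect_equal(sum(w$window == "cue"), 10)      # floor(2.0 * 5)
  expect_equal(sum(w$window == "reward"), 10)
  # constant offset removed by the trial's own baseline mean
  expect_equal(mean(w$glutamate_uM[w$window == "baseline"]), 0, tolerance = 1e-12)
  expect_equal(max(w$glutamate_uM[w$window == "cue"]), 8, tolerance = 8 * 0.06)
  expect_true(all(w$degenerate_sd))

  # constant trace: all corrected windows identically zero
  conc0 <- structure(list(time = t, glutamate = rep(3, length(t)),
                          normalization_applied = FALSE),
                     class = "concentration_trace")
  w0 <- extract_windows(conc0, events)
  expect_true(all(w0$glutamate_uM == 0))
})

test_that("windows have no look-ahead and edge events are skipped, not fatal", {
  t <- seq(0, 59.8, by = 0.2)
  g <- sin(t)
  conc <- structure(list(time = t, glutamate = g, normalization_applied = FALSE),
                    class = "concentration_trace")
  events <- data.frame(trial = 1, cue_onset_s = 30, reward_s = NA)
  w1 <- extract_windows(conc, events)
  # corrupt samples after the cue window: baseline and cue are unchanged
  g2 <- g
  g2[t >= 33] <- 99
  conc2 <- conc
  conc2$glutamate <- g2
  w2 <- extract_windows(conc2, events)
  expect_equal(w2$glutamate_uM, w1$glutamate_uM)
  # corrupt pre-baseline samples: still unchanged
  g3 <- g
  g3[t < 27] <- -99
  conc3 <- conc
  conc3$glutamate <- g3
  expect_equal(extract_windows(conc3, events)$glutamate_uM, w1$glutamate_uM)

  # events too close to the trace edges are skipped and logged
  edge_events <- data.frame(trial = 1:3, cue_onset_s = c(1, 30, 59.5),
                            reward_s = c(NA, 59.5, NA))
  we <- extract_windows(conc, edge_events)
  expect_equal(sort(unique(we$trial)), 2)
  expect_equal(nrow(attr(we, "skipped")), 3)
})

test_that("QC-flagged traces are dropped with exclusion counts", {
  cfg <- default_generator_config()
  sess <- gen_cttt_session(cfg, "GT", seed = 41)
  traces <- lapply(1:3, function(i) gen_glutamate_trace(sess, cfg, seed = 40 + i))
  traces[[2]]$metadata$qc$artifact_detected <- TRUE
  traces[[3]]$metadata$qc$placement_rejected <- TRUE
  kept <- filter_traces(traces)
  expect_length(kept, 1)
  excl <- attr(kept, "excluded")
  expect_equal(unname(excl["artifact_detected"]), 1, ignore_attr = TRUE)
  expect_equal(unname(excl["placement_rejected"]), 1, ignore_attr = TRUE)
})

test_that("processing is linear in the input currents", {
  cfg <- default_generator_config()
  cal <- noiseless_calibration()
  sess <- gen_cttt_session(cfg, "GT", seed = 21)
  tr <- gen_glutamate_trace(sess, cfg, seed = 22)
  a <- 2.5
  tr_scaled <- tr
  tr_scaled$active <- a * tr$active
  tr_scaled$sentinel <- a * tr$sentinel
  c1 <- process_trace(tr, cal)
  c2 <- process_trace(tr_scaled, cal)
  expect_equal(c2$glutamate, a * c1$glutamate, tolerance = 1e-12)
})
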