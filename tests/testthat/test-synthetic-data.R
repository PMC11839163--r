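test_that("session generation is deterministic and schedule invariants hold", {
  cfg <- default_generator_config()
  a <- gen_cttt_session(cfg, "GT", seed = 11)
  b <- gen_cttt_session(cfg, "GT", seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, gen_cttt_session(cfg, "GT", seed = 12)))
  expect_equal(nrow(a$trials), 18)

  for (seed in 1:100) {
    s <- gen_cttt_session(cfg, if (seed %% 2) "GT" else "ST", seed = seed)
    tr <- s$trials
    # no run of three same-modality cues
    expect_lte(max(rle(tr$modality)$lengths), 2)
    # ITIs within 60 +/- 45 s
    block <- cfg$cue_duration + cfg$stop_delay + cfg$pause_duration
    itis <- diff(c(-block, tr$cue_onset_s)) - block
    expect_true(all(itis >= 15 - 1e-9 & itis <= 105 + 1e-9))
    # timeline constants
    expect_equal(tr$cue_offset_s - tr$cue_onset_s, rep(2, 18))
    expect_equal(tr$treadmill_stop_s - tr$cue_offset_s, rep(1, 18))
    expect_equal(tr$pause_end_s - tr$treadmill_stop_s, rep(5, 18))
  }
})

test_that("invalid generator inputs are rejected", {
  cfg <- default_generator_config()
  expect_error(gen_cttt_session(cfg, "XX", seed = 1), "unknown phenotype")
  expect_error(gen_pca_sessions("GT", n_sessions = 0), ">= 1")
  bad <- cfg
  bad$phenotypes$GT$turn_prob <- 1.4
  expect_error(validate_generator_config(bad), "probability")
  el <- cfg$electrode
  el$sensitivity <- -1
  expect_error(gen_calibration_series(electrode = el), ">= 0")
})

test_that("sentinel channel carries shared components only (noiseless conservation)", {
  cfg <- default_generator_config()
  cfg$noise_sd <- 0
  sess <- gen_cttt_session(cfg, "ST", seed = 3)
  tr <- gen_glutamate_trace(sess, cfg, seed = 4)
  net <- sentinel_subtract(tr)
  # reconstruct the injected transients from the recorded truth
  truth <- tr$metadata$truth
  expected <- numeric(length(tr$time))
  apex_dt <- cfg$pulse_rise * cfg$pulse_decay / (cfg$pulse_decay - cfg$pulse_rise) *
    log(cfg$pulse_decay / cfg$pulse_rise)
  for (k in seq_len(nrow(truth))) {
    expected <- expected + truth$amplitude_uM[k] *
      transient_pulse(tr$time - (truth$apex_s[k] - apex_dt),
                      cfg$pulse_rise, cfg$pulse_decay)
  }
  # drift and shared artifacts cancel exactly: net equals the injected
  # transients alone, and is numerically zero far from any apex
  expect_equal(net, cfg$electrode$sensitivity * expected, tolerance = 1e-12)
  far <- vapply(tr$time, function(t) all(abs(t - truth$apex_s) > 10), logical(1))
  expect_true(any(far))
  expect_true(all(abs(net[far]) < 1e-6))
})

test_that("trace generation is deterministic and rejects too-short durations", {
  cfg <- default_generator_config()
  sess <- gen_cttt_session(cfg, "GT", seed = 1)
  a <- gen_glutamate_trace(sess, cfg, seed = 2)
  b <- gen_glutamate_trace(sess, cfg, seed = 2)
  expect_identical(a, b)
  expect_error(gen_glutamate_trace(sess, cfg, seed = 2, duration = 10),
               "beyond")
})

test_that("calibration series has exact plateau structure and determinism", {
  s <- gen_calibration_series(noise_sd = 0, seed = 1)
  # noiseless plateaus: shifts of 240/480/720 pA at 20/40/60 uM (12 pA/uM)
  plateau_at <- function(tmax) mean(s$active[s$time >= tmax - 10 & s$time < tmax])
  base <- plateau_at(60)
  aa <- plateau_at(120)
  expect_equal(aa - base, 12 / 113.1 * 250, tolerance = 1e-6)
  expect_equal(plateau_at(180) - aa, 240, tolerance = 1e-6)
  expect_equal(plateau_at(240) - aa, 480, tolerance = 1e-6)
  expect_equal(plateau_at(300) - aa, 720, tolerance = 1e-6)
  expect_identical(s, gen_calibration_series(noise_sd = 0, seed = 1))
  s2 <- gen_calibration_series(noise_sd = 1.2, seed = 9)
  expect_identical(s2, gen_calibration_series(noise_sd = 1.2, seed = 9))
})

test_that("PCA session generation matches its presets", {
  p <- gen_pca_sessions("GT", n_sessions = 5, seed = 2)
  expect_equal(nrow(p), 5 * 25)
  expect_equal(unname(table(p$session)), rep(25L, 5), ignore_attr = TRUE)
  pure_st <- gen_pca_sessions("pure_ST", n_sessions = 1, seed = 1)
  expect_true(all(pure_st$lever_contacts >= 1))
  expect_true(all(pure_st$cs_port_entries == 0))
  pure_gt <- gen_pca_sessions("pure_GT", n_sessions = 1, seed = 1)
  expect_true(all(pure_gt$lever_contacts == 0))
  expect_true(all(pure_gt$cs_port_entries >= 1))
  expect_identical(gen_pca_sessions("ST", 5, seed = 3),
                   gen_pca_sessions("ST", 5, seed = 3))
})

test_that("trace files and event logs round-trip through CSV", {
  cfg <- default_generator_config()
  sess <- gen_cttt_session(cfg, "ST", seed = 8)
  tr <- gen_glutamate_trace(sess, cfg, seed = 9)
  tdir <- withr::local_tempdir()
  tpath <- file.path(tdir, "trace.csv")
  write_trace_csv(tr, tpath)
  back <- read_trace_csv(tpath)
  expect_equal(back$active, tr$active)
  expect_equal(back$metadata$da_response, tr$metadata$da_response)
  epath <- file.path(tdir, "events.csv")
  write_event_log_csv(sess, epath)
  back_s <- read_event_log_csv(epath)
  expect_equal(back_s$trials$cue_onset_s, sess$trials$cue_onset_s)
  expect_equal(back_s$phenotype, "ST")
  cpath <- file.path(tdir, "calib.csv")
  s <- gen_calibration_series(noise_sd = 0.5, seed = 2)
  write_calibration_csv(s, cpath)
  back_c <- read_calibration_csv(cpath)
  expect_equal(fit_calibration(back_c)$sensitivity,
               fit_calibration(s)$sensitivity)
})
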