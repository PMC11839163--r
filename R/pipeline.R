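#' Default end-to-end run configuration
#'
#' Bundles the generator block, the processing constants (2.5-s baseline,
#' 2-s cue and reward windows, 3-SD peak threshold with 1-SD drops at 5 Hz),
#' and the sweep block (threshold grid, peak classes, minimum cell count 10)
#' with cohort sizes for a synthetic run.
#'
#' @param seed run seed, fanned out to stages via [child_seed()].
#' @param n_rats named list: rats per phenotype.
#' @param n_sessions CTTT sessions generated per rat.
#' @return a list of class `run_config`.
#' @export
default_run_config <- function(seed = 1,
                               n_rats = list(GT = 3, ST = 3),
                               n_sessions = 2) {
  cfg <- list(
    seed = seed,
    n_rats = n_rats,
    n_sessions = n_sessions,
    generator = default_generator_config(),
    calibration = list(noise_sd = 1.2, plateau_window = 10),
    processing = list(baseline_duration = 2.5, cue_duration = 2.0,
                      reward_duration = 2.0),
    sweep = list(thresholds = c(2, 2.8, 4, 6, 8),
                 classes = c("any", "single", "multi"),
                 min_cell = 10)
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname default_run_config
#' @param config a run configuration to validate.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (!is_scalar_number(config$seed)) stop("seed must be a number", call. = FALSE)
  if (any(unlist(config$n_rats) < 1)) stop("n_rats must be >= 1", call. = FALSE)
  if (config$n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  if (config$sweep$min_cell < 0) stop("min_cell must be >= 0", call. = FALSE)
  validate_generator_config(config$generator)
  class(config) <- "run_config"
  config
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' Orchestrates generate, calibrate, process, detect, score and sweep:
#' per rat, a calibration series is generated and fitted; per session, a
#' CTTT schedule and a dual-channel trace are generated, sentinel-subtracted,
#' dopamine-normalized where the electrode responds, converted to uM,
#' windowed around cue onsets and reward deliveries, and peak features are
#' extracted; sessions are behaviorally scored; the turn-cue features feed
#' the contingency threshold sweep. Identical (config, seed) reruns produce
#' identical outputs; stage seeds derive from the run seed via
#' [child_seed()].
#'
#' @param config a [default_run_config()] list.
#' @param out_dir output directory (created if needed); stage tables are
#'   written as CSV plus a JSON run manifest.
#' @param quiet suppress per-stage log lines.
#' @return the run manifest (invisibly): config hash, seed, per-stage record
#'   counts, and the output file inventory.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed
  gen <- config$generator
  proc <- config$processing

  calib_rows <- list()
  feature_rows <- list()
  outcome_rows <- list()
  summary_rows <- list()
  pca_rows <- list()
  n_windows_skipped <- 0

  for (ph in names(config$n_rats)) {
    for (r in seq_len(config$n_rats[[ph]])) {
      rat <- sprintf("%s%02d", ph, r)

      series <- gen_calibration_series(
        electrode = gen$electrode,
        noise_sd = config$calibration$noise_sd,
        seed = child_seed(seed, "calibration", rat))
      calib <- fit_calibration(series,
                               plateau_window = config$calibration$plateau_window)
      calib_rows[[rat]] <- data.frame(
        rat_id = rat, phenotype = ph,
        sensitivity = calib$sensitivity, linearity_r = calib$linearity_r,
        lod = calib$lod, selectivity = calib$selectivity,
        da_response = calib$da_response, passed = calib$passed$overall,
        stringsAsFactors = FALSE)

      pca <- gen_pca_sessions(ph, n_sessions = 5,
                              seed = child_seed(seed, "pca", rat),
                              rat_id = rat)
      scores <- score_pca(pca)
      pca_rows[[rat]] <- attr(scores, "labels")

      for (s in seq_len(config$n_sessions)) {
        session <- gen_cttt_session(gen, ph,
                                    seed = child_seed(seed, "session", rat, s))
        trace <- gen_glutamate_trace(session, gen, ph,
                                     seed = child_seed(seed, "trace", rat, s),
                                     electrode_id = rat)
        conc <- process_trace(trace, calib)
        windows <- extract_windows(conc, session,
                                   baseline_duration = proc$baseline_duration,
                                   cue_duration = proc$cue_duration,
                                   reward_duration = proc$reward_duration)
        skipped <- attr(windows, "skipped")
        n_windows_skipped <- n_windows_skipped +
          if (is.null(skipped)) 0 else nrow(skipped)
        feats <- window_peak_features(windows)
        scored <- score_session(session)
        feats <- merge(feats,
                       scored[, c("trial", "role", "scored_outcome")],
                       by = "trial")
        feats$rat_id <- rat
        feats$phenotype <- ph
        feats$session <- s
        feature_rows[[paste(rat, s)]] <- feats

        scored$rat_id <- rat
        scored$phenotype <- ph
        scored$session <- s
        outcome_rows[[paste(rat, s)]] <- scored
        summ <- summarize_session(scored)
        summary_rows[[paste(rat, s)]] <- data.frame(
          rat_id = rat, phenotype = ph, session = s,
          turn_ratio = summ$turn_ratio, stop_ratio = summ$stop_ratio,
          mean_initiation = summ$mean_initiation,
          mean_completion = summ$mean_completion,
          mean_turn_duration = summ$mean_turn_duration,
          stringsAsFactors = FALSE)
      }
    }
  }

  calibration <- do.call(rbind, calib_rows)
  features <- do.call(rbind, feature_rows)
  outcomes <- do.call(rbind, outcome_rows)
  summaries <- do.call(rbind, summary_rows)
  pca_labels <- do.call(rbind, pca_rows)
  say("generated %d rats, %d sessions, %d event windows (%d skipped)",
      nrow(calibration), nrow(summaries), nrow(features), n_windows_skipped)

  # contingency sweep over turn-cue traces (turn vs miss)
  turn_feats <- features[features$event_kind == "cue" &
                           features$role == "turn" &
                           features$scored_outcome %in% c("cued_turn", "miss"), ,
                         drop = FALSE]
  turn_feats$outcome <- ifelse(turn_feats$scored_outcome == "cued_turn",
                               "turn", "miss")
  sweep <- threshold_sweep(turn_feats,
                           thresholds = config$sweep$thresholds,
                           peak_classes = config$sweep$classes,
                           min_cell = config$sweep$min_cell)
  say("sweep: %d conditions, %d included", nrow(sweep), sum(sweep$included))

  paths <- c(calibration = "calibration.csv", features = "features.csv",
             outcomes = "outcomes.csv", session_summaries = "session_summaries.csv",
             pca_labels = "pca_labels.csv", sweep = "sweep.csv")
  paths[] <- file.path(out_dir, paths)
  write.csv(calibration, paths["calibration"], row.names = FALSE)
  write.csv(features, paths["features"], row.names = FALSE)
  write.csv(outcomes, paths["outcomes"], row.names = FALSE)
  write.csv(summaries, paths["session_summaries"], row.names = FALSE)
  write.csv(pca_labels, paths["pca_labels"], row.names = FALSE)
  write.csv(as.data.frame(sweep), paths["sweep"], row.names = FALSE)

  manifest <- list(
    config_hash = config_hash(config),
    seed = seed,
    counts = list(
      rats = nrow(calibration),
      electrodes_passed = sum(calibration$passed),
      sessions = nrow(summaries),
      traces = nrow(features),
      traces_with_peaks = sum(features$n_peaks > 0),
      windows_skipped = n_windows_skipped,
      sweep_conditions = nrow(sweep),
      sweep_included = sum(sweep$included)
    ),
    files = as.list(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
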