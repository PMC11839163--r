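#' Sentinel-channel background subtraction
#'
#' Subtracts the current recorded on the enzyme-free sentinel site from the
#' current on the active (glutamate oxidase-coated) site, removing shared
#' background components (baseline, drift, electrostatic artifacts).
#'
#' @param trace a `dual_channel_trace`, or a list with numeric `active` and
#'   `sentinel` of equal length.
#' @return net current in pA, same length as the inputs.
#' @export
sentinel_subtract <- function(trace) {
  if (length(trace$active) != length(trace$sentinel)) {
    stop("active and sentinel channels differ in length", call. = FALSE)
  }
  trace$active - trace$sentinel
}

#' Dopamine-response normalization of net currents
#'
#' Electrodes whose exclusion layer passes dopamine (in-vitro dopamine
#' response above 0.1 pA) have their net currents divided by that response,
#' correcting for variation in barrier efficacy; other electrodes pass
#' through unchanged.
#'
#' @param net net current series (pA).
#' @param da_response in-vitro dopamine-evoked current in pA (>= 0).
#' @return list with `values` and logical `normalized`.
#' @export
dopamine_normalize <- function(net, da_response) {
  if (!is_scalar_number(da_response) || da_response < 0) {
    stop("da_response must be a non-negative number", call. = FALSE)
  }
  if (da_response > 0.1) {
    list(values = net / da_response, normalized = TRUE)
  } else {
    list(values = net, normalized = FALSE)
  }
}

#' Convert net current to glutamate concentration
#'
#' Divides the (optionally dopamine-normalized) net current by the
#' calibration slope. When the series was normalized, the slope is divided
#' by the same dopamine response, so the resulting concentration is
#' invariant to normalization for matched electrode constants.
#'
#' @param net net current series; either raw pA or dopamine-normalized.
#' @param calibration a `calibration_result`; must have passed the
#'   acceptance criteria unless `check_passed = FALSE`.
#' @param normalized was `net` dopamine-normalized?
#' @param time optional sample times, carried into the output.
#' @param check_passed enforce the electrode acceptance criteria.
#' @return an object of class `concentration_trace`: list with `time`,
#'   `glutamate` (uM) and `normalization_applied`.
#' @export
to_concentration <- function(net, calibration, normalized = FALSE,
                             time = NULL, check_passed = TRUE) {
  stopifnot(inherits(calibration, "calibration_result"))
  if (check_passed && !isTRUE(calibration$passed$overall)) {
    stop("calibration did not pass the electrode acceptance criteria",
         call. = FALSE)
  }
  slope <- calibration$sensitivity
  if (normalized) slope <- slope / calibration$da_response
  if (!is_scalar_number(slope) || slope <= 0) {
    stop("calibration slope must be positive", call. = FALSE)
  }
  structure(list(time = time, glutamate = net / slope,
                 normalization_applied = normalized),
            class = "concentration_trace")
}

#' Full current-to-concentration processing of one trace
#'
#' Convenience chain: sentinel subtraction, dopamine normalization (decided
#' by the calibration's dopamine response), conversion to uM.
#'
#' @param trace a `dual_channel_trace`.
#' @param calibration a `calibration_result` for the same electrode.
#' @inheritParams to_concentration
#' @return a `concentration_trace`.
#' @export
process_trace <- function(trace, calibration, check_passed = TRUE) {
  net <- sentinel_subtract(trace)
  # a measured dopamine plateau shift at or below zero is no response
  norm <- dopamine_normalize(net, max(0, calibration$da_response))
  to_concentration(norm$values, calibration, normalized = norm$normalized,
                   time = trace$time, check_passed = check_passed)
}

#' Extract event-anchored baseline / cue / reward windows
#'
#' For each trial, takes the 2.5 s preceding cue onset as the baseline
#' window, the 2 s from cue onset as the cue window, and (on rewarded
#' trials) the 2 s from reward delivery as the reward window. Windows are
#' half-open `[anchor, anchor + duration)` with the anchor snapped to the
#' nearest sample at or after the event time, so at 5 Hz the baseline holds
#' 12 samples and cue/reward windows 10. Cue and reward values are
#' baseline-corrected by subtracting the mean of the trial's own baseline
#' window; each window carries the baseline mean and SD (in uM). A baseline
#' SD of exactly zero (noiseless synthetic traces) is floored at machine
#' epsilon and flagged, keeping downstream peak thresholds defined. Events
#' too close to the trace edge are skipped and logged, not fatal.
#'
#' @param conc a `concentration_trace` with sample times.
#' @param events event log: data frame with `trial`, `cue_onset_s` and
#'   optionally `reward_s` (a `cttt_session` is also accepted).
#' @param baseline_duration,cue_duration,reward_duration window lengths (s).
#' @return an object of class `event_window_set`: a long data frame with
#'   columns `trial`, `window` (baseline/cue/reward), `sample`, `t_rel_s`,
#'   `glutamate_uM` (baseline-corrected), `baseline_mean`, `baseline_sd`,
#'   `degenerate_sd`; skipped events in attribute `"skipped"`.
#' @export
extract_windows <- function(conc, events,
                            baseline_duration = 2.5,
                            cue_duration = 2.0,
                            reward_duration = 2.0) {
  if (inherits(events, "cttt_session")) events <- events$trials
  stopifnot(inherits(conc, "concentration_trace"), !is.null(conc$time))
  time <- conc$time
  g <- conc$glutamate
  fs <- 1 / (time[2] - time[1])
  n <- length(time)

  n_base <- floor(baseline_duration * fs)
  n_cue <- floor(cue_duration * fs)
  n_rew <- floor(reward_duration * fs)

  snap_at_or_after <- function(t) {
    idx <- ceiling((t - time[1]) * fs - 1e-9) + 1
    as.integer(idx)
  }

  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(events))) {
    trial <- events$trial[i]
    cue_idx <- snap_at_or_after(events$cue_onset_s[i])
    base_idx <- (cue_idx - n_base):(cue_idx - 1)
    cue_win <- cue_idx:(cue_idx + n_cue - 1)
    if (min(base_idx) < 1 || max(cue_win) > n) {
      skipped[[length(skipped) + 1]] <- data.frame(trial = trial, window = "cue")
      next
    }
    b_mean <- mean(g[base_idx])
    b_sd <- sd(g[base_idx])
    degenerate <- b_sd <= 0
    if (degenerate) b_sd <- .Machine$double.eps

    # t_rel_s is relative to the true event time (cue onset / reward
    # delivery), not the snapped anchor sample, so latencies read from the
    # windows are unbiased by the sub-sample anchor offset
    add_window <- function(kind, idx, anchor_time) {
      data.frame(trial = trial, window = kind, sample = seq_along(idx),
                 t_rel_s = time[idx] - anchor_time,
                 glutamate_uM = g[idx] - b_mean,
                 baseline_mean = b_mean, baseline_sd = b_sd,
                 degenerate_sd = degenerate,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- add_window("baseline", base_idx, events$cue_onset_s[i])
    rows[[length(rows) + 1]] <- add_window("cue", cue_win, events$cue_onset_s[i])

    rew <- if ("reward_s" %in% names(events)) events$reward_s[i] else NA
    if (!is.na(rew)) {
      rew_idx <- snap_at_or_after(rew)
      rew_win <- rew_idx:(rew_idx + n_rew - 1)
      if (max(rew_win) > n) {
        skipped[[length(skipped) + 1]] <- data.frame(trial = trial, window = "reward")
      } else {
        rows[[length(rows) + 1]] <- add_window("reward", rew_win, rew)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(), window = character(), sample = integer(),
               t_rel_s = numeric(), glutamate_uM = numeric(),
               baseline_mean = numeric(), baseline_sd = numeric(),
               degenerate_sd = logical())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "sampling_rate") <- fs
  class(out) <- c("event_window_set", class(out))
  out
}

#' Write an event-window set to CSV
#'
#' @param windows an `event_window_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  write.csv(as.data.frame(windows), path, row.names = FALSE)
  invisible(path)
}
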