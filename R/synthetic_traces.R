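#' Normalized glutamate transient pulse
#'
#' Double-exponential waveform with a fast rise and slower decay, normalized
#' to a unit apex, used to inject glutamate transients into synthetic traces.
#' Returns zero for `t < 0`.
#'
#' @param t time in seconds relative to pulse onset.
#' @param rise rise time constant in s.
#' @param decay decay time constant in s (must exceed `rise`).
#' @return pulse values in [0, 1].
#' @export
transient_pulse <- function(t, rise = 0.25, decay = 0.45) {
  stopifnot(decay > rise, rise > 0)
  apex <- pulse_apex_time(rise, decay)
  peak <- exp(-apex / decay) - exp(-apex / rise)
  out <- ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / peak)
  pmax(out, 0)
}

# time from pulse onset to apex
pulse_apex_time <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

#' Generate a synthetic dual-channel glutamate trace for a CTTT session
#'
#' Emulates a 5 Hz two-channel amperometric recording spanning a behavioral
#' session. Both channels share a common baseline current, slow drift, and
#' rectangular electrostatic artifacts; glutamate transients (double
#' exponential pulses scaled by the electrode sensitivity) are injected into
#' the active channel only, anchored to cue onsets and reward deliveries.
#' Cue-locked structure is phenotype dependent: with probability
#' `1 - single_peak_prob` a trace carries two or three cue-locked peaks whose
#' second and third apex latencies are drawn from the configured normal laws
#' (defaults 1.58 +/- 0.39 s and 1.83 +/- 0.25 s after cue onset), truncated
#' so that successive apexes stay at least `min_peak_separation` apart
#' (distinct local maxima are not resolvable below that separation at 5 Hz).
#' Channel noise is independent between channels, so in the noiseless limit
#' active - sentinel recovers the injected transients exactly.
#'
#' @param session a `cttt_session` from [gen_cttt_session()].
#' @param config a [default_generator_config()] list.
#' @param phenotype phenotype label; defaults to the session's.
#' @param seed integer seed.
#' @param duration optional total trace duration in s; must cover all session
#'   events (error otherwise). Default: last event + `config$trial_tail`.
#' @param electrode_id identifier stored in the metadata.
#' @return a [new_dual_channel_trace()] object; `metadata$truth` records the
#'   injected peaks (trial, kind, apex time, amplitude in uM).
#' @export
gen_glutamate_trace <- function(session,
                                config = default_generator_config(),
                                phenotype = session$phenotype,
                                seed = 1,
                                duration = NULL,
                                electrode_id = "E01") {
  validate_generator_config(config)
  params <- phenotype_params(config, phenotype)
  trials <- session$trials
  if (nrow(trials) == 0) stop("session schedule is empty", call. = FALSE)

  last_event <- max(trials$pause_end_s, trials$reward_s, na.rm = TRUE)
  if (is.null(duration)) {
    duration <- last_event + config$trial_tail
  } else if (duration < last_event) {
    stop("schedule events extend beyond the requested trace duration",
         call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- floor(duration * fs) + 1
  time <- (seq_len(n) - 1) / fs

  withr::with_seed(seed, {
    # shared background: baseline + drift + artifacts
    shared <- config$baseline_current + config$drift_rate * time
    n_art <- rpois(1, config$artifact_rate * duration / 60)
    if (n_art > 0) {
      onsets <- runif(n_art, 0, duration - config$artifact_duration)
      for (o in onsets) {
        shared <- shared + config$artifact_amplitude *
          (time >= o & time < o + config$artifact_duration)
      }
    }

    truth <- draw_event_peaks(trials, params, config)

    glut_uM <- numeric(n)
    if (nrow(truth) > 0) {
      onset <- truth$apex_s - pulse_apex_time(config$pulse_rise, config$pulse_decay)
      for (k in seq_len(nrow(truth))) {
        glut_uM <- glut_uM + truth$amplitude_uM[k] *
          transient_pulse(time - onset[k], config$pulse_rise, config$pulse_decay)
      }
    }

    active <- shared + config$electrode$sensitivity * glut_uM +
      rnorm(n, 0, config$noise_sd)
    sentinel <- shared + rnorm(n, 0, config$noise_sd)

    new_dual_channel_trace(time, active, sentinel, metadata = list(
      electrode_id = electrode_id,
      sampling_rate = fs,
      da_response = config$electrode$da_response,
      sensitivity = config$electrode$sensitivity,
      phenotype = phenotype,
      truth = truth
    ))
  })
}

# Draw the injected-peak table for a session: cue-locked peaks for every cue
# presentation and reward-locked peaks on rewarded trials. Runs under the
# caller's RNG state.
draw_event_peaks <- function(trials, params, config) {
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    cue <- trials$cue_onset_s[i]
    multi <- runif(1) >= params$single_peak_prob
    if (multi) {
      n_extra <- sample(seq_along(params$extra_peak_count_probs), 1,
                        prob = params$extra_peak_count_probs)
      first <- cue + rtruncnorm(1, config$multi_first_peak_latency_mean,
                                config$multi_first_peak_latency_sd,
                                config$multi_first_peak_latency_range[1],
                                config$multi_first_peak_latency_range[2])
      apexes <- first
      for (k in seq_len(n_extra)) {
        lo <- apexes[length(apexes)] - cue + config$min_peak_separation
        apexes <- c(apexes, cue + rtruncnorm(1,
                                             params$extra_peak_latency_means[k],
                                             params$extra_peak_latency_sds[k],
                                             lo, Inf))
      }
      amps <- c(rtruncnorm(1, params$peak_amplitude_mean,
                           params$peak_amplitude_sd, 0.5, Inf),
                rtruncnorm(n_extra,
                           params$peak_amplitude_mean * params$extra_peak_amplitude_scale,
                           params$peak_amplitude_sd * params$extra_peak_amplitude_scale,
                           0.5, Inf))
      rows[[length(rows) + 1]] <- data.frame(
        trial = trials$trial[i], kind = "cue", peak = seq_along(apexes),
        apex_s = apexes, amplitude_uM = amps)
    } else {
      apex <- cue + rtruncnorm(1, config$first_peak_latency_mean,
                               config$first_peak_latency_sd,
                               config$first_peak_latency_range[1],
                               config$first_peak_latency_range[2])
      amp <- rtruncnorm(1, params$peak_amplitude_mean,
                        params$peak_amplitude_sd, 0.5, Inf)
      rows[[length(rows) + 1]] <- data.frame(
        trial = trials$trial[i], kind = "cue", peak = 1L,
        apex_s = apex, amplitude_uM = amp)
    }
    if (!is.na(trials$reward_s[i]) && runif(1) < params$reward_peak_prob) {
      apex <- trials$reward_s[i] + rtruncnorm(1, config$first_peak_latency_mean,
                                              config$first_peak_latency_sd,
                                              config$first_peak_latency_range[1],
                                              config$first_peak_latency_range[2])
      amp <- rtruncnorm(1, params$reward_peak_amplitude_mean,
                        params$reward_peak_amplitude_sd, 0.5, Inf)
      rows[[length(rows) + 1]] <- data.frame(
        trial = trials$trial[i], kind = "reward", peak = 1L,
        apex_s = apex, amplitude_uM = amp)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(trial = integer(), kind = character(), peak = integer(),
                      apex_s = numeric(), amplitude_uM = numeric()))
  }
  do.call(rbind, rows)
}

#' Write / read a CTTT event log as CSV
#'
#' @param session a `cttt_session` (or its `trials` data frame).
#' @param path CSV file path.
#' @return the path / a `cttt_session` with phenotype taken from the file's
#'   companion columns when present.
#' @export
write_event_log_csv <- function(session, path) {
  trials <- if (inherits(session, "cttt_session")) session$trials else session
  df <- trials
  df$phenotype <- if (inherits(session, "cttt_session")) session$phenotype else NA
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log_csv
#' @export
read_event_log_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  phenotype <- if ("phenotype" %in% names(df)) df$phenotype[1] else NA_character_
  df$phenotype <- NULL
  structure(list(trials = df, phenotype = phenotype,
                 turn_cue_modality = df$modality[match("turn", df$role)]),
            class = "cttt_session")
}
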