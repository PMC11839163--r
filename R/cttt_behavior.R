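#' Score a single CTTT trial
#'
#' Applies the timing rules of the Cued-Triggered Turning Task to one trial's
#' event record. On turn-cue trials, a cued turn requires a turn initiation
#' within 8 s of cue onset (the treadmill restart; initiation exactly at
#' 8.0 s counts), otherwise the trial is a miss. On stop-cue trials, a turn
#' during the 5-s treadmill pause is a false turn; otherwise the trial is a
#' cued stop when stopping was observed, and an unclassified cued-stop
#' record (flagged) when neither a stop nor a turn was recorded. The turn
#' itself (a body rotation of at least 90 degrees) is a video judgment
#' carried in the event log; only the timing rules are applied here.
#'
#' @param trial a list or one-row data frame with `role` ("turn"/"stop"),
#'   `cue_onset_s`, `treadmill_stop_s`, `pause_end_s`, `turn_init_s`,
#'   `turn_complete_s` (times in s, `NA` when absent), and optionally
#'   `stop_observed` (defaults to `TRUE` on stop trials without a turn).
#' @param turn_bound response bound in s from cue onset (default 8).
#' @return a list: `outcome` (`cued_turn`, `miss`, `cued_stop`,
#'   `false_turn`), `initiation_latency`, `completion_latency` (s from cue
#'   onset, `NA` when absent) and `unclassified` flag.
#' @export
score_trial <- function(trial, turn_bound = 8) {
  trial <- as.list(trial)
  init <- trial$turn_init_s
  comp <- trial$turn_complete_s
  if (!is.na(init) && !is.na(comp) && comp < init) {
    stop("turn completion precedes initiation", call. = FALSE)
  }
  onset <- trial$cue_onset_s
  unclassified <- FALSE
  if (trial$role == "turn") {
    outcome <- if (!is.na(init) && init <= onset + turn_bound) "cued_turn" else "miss"
  } else if (trial$role == "stop") {
    turned_in_pause <- !is.na(init) &&
      init >= trial$treadmill_stop_s && init <= trial$pause_end_s
    if (turned_in_pause) {
      outcome <- "false_turn"
    } else {
      stop_observed <- trial$stop_observed %||% TRUE
      outcome <- "cued_stop"
      unclassified <- !isTRUE(stop_observed)
    }
  } else {
    stop(sprintf("unknown cue role '%s'", trial$role), call. = FALSE)
  }
  list(
    outcome = outcome,
    initiation_latency = if (outcome %in% c("cued_turn", "false_turn") && !is.na(init)) {
      init - onset
    } else {
      NA_real_
    },
    completion_latency = if (outcome %in% c("cued_turn", "false_turn") && !is.na(comp)) {
      comp - onset
    } else {
      NA_real_
    },
    unclassified = unclassified
  )
}

#' Score every trial of a session
#'
#' @param session a `cttt_session` or its `trials` data frame.
#' @inheritParams score_trial
#' @return the trials data frame with `scored_outcome`,
#'   `initiation_latency`, `completion_latency`, `unclassified` appended.
#' @export
score_session <- function(session, turn_bound = 8) {
  trials <- if (inherits(session, "cttt_session")) session$trials else session
  res <- lapply(seq_len(nrow(trials)), function(i) {
    score_trial(trials[i, , drop = FALSE], turn_bound = turn_bound)
  })
  trials$scored_outcome <- vapply(res, `[[`, character(1), "outcome")
  trials$initiation_latency <- vapply(res, `[[`, numeric(1), "initiation_latency")
  trials$completion_latency <- vapply(res, `[[`, numeric(1), "completion_latency")
  trials$unclassified <- vapply(res, `[[`, logical(1), "unclassified")
  trials
}

#' Summarize scored trial outcomes into session measures
#'
#' Computes the turns-per-turn-cue-trial and stops-per-stop-cue-trial
#' ratios, mean turn initiation and completion latencies over cued turns,
#' and the mean turn duration (completion minus initiation).
#'
#' @param outcomes a scored trials data frame from [score_session()].
#' @return a list of class `cttt_session_summary`. A ratio whose trial type
#'   is absent is reported as `NA` (missing marker).
#' @export
summarize_session <- function(outcomes) {
  stopifnot("scored_outcome" %in% names(outcomes))
  turn_trials <- sum(outcomes$role == "turn")
  stop_trials <- sum(outcomes$role == "stop")
  turns <- sum(outcomes$scored_outcome == "cued_turn")
  stops <- sum(outcomes$scored_outcome == "cued_stop" & !outcomes$unclassified)
  is_turn <- outcomes$scored_outcome == "cued_turn"
  dur <- outcomes$completion_latency[is_turn] - outcomes$initiation_latency[is_turn]
  structure(list(
    n_turn_trials = turn_trials,
    n_stop_trials = stop_trials,
    turn_ratio = if (turn_trials > 0) turns / turn_trials else NA_real_,
    stop_ratio = if (stop_trials > 0) stops / stop_trials else NA_real_,
    n_false_turns = sum(outcomes$scored_outcome == "false_turn"),
    mean_initiation = mean(outcomes$initiation_latency[is_turn], na.rm = TRUE),
    mean_completion = mean(outcomes$completion_latency[is_turn], na.rm = TRUE),
    mean_turn_duration = mean(dur, na.rm = TRUE)
  ), class = "cttt_session_summary")
}

#' @export
print.cttt_session_summary <- function(x, ...) {
  cat(sprintf("CTTT session: %.2f turns/turn cue trials (n=%d), %.2f stops/stop cue trials (n=%d)\n",
              x$turn_ratio, x$n_turn_trials, x$stop_ratio, x$n_stop_trials))
  cat(sprintf("  turn initiation %.2f s, completion %.2f s, duration %.2f s\n",
              x$mean_initiation, x$mean_completion, x$mean_turn_duration))
  invisible(x)
}

#' Learning-criterion detection over a session history
#'
#' The acquisition criterion is 70% correct responses to either cue — both
#' the turn ratio and the stop ratio at or above 0.70 — for two consecutive
#' sessions.
#'
#' @param history a data frame with `turn_ratio` and `stop_ratio` per
#'   session (in order), or a list of `cttt_session_summary`.
#' @param threshold criterion ratio (default 0.70).
#' @return list with `reached` (logical) and `session` (index of the second
#'   qualifying session, `NA` when never reached).
#' @export
criterion_reached <- function(history, threshold = 0.70) {
  if (!is.data.frame(history)) {
    history <- data.frame(
      turn_ratio = vapply(history, `[[`, numeric(1), "turn_ratio"),
      stop_ratio = vapply(history, `[[`, numeric(1), "stop_ratio")
    )
  }
  if (nrow(history) == 0) stop("history is empty", call. = FALSE)
  ok <- history$turn_ratio >= threshold & history$stop_ratio >= threshold
  ok[is.na(ok)] <- FALSE
  hit <- which(ok[-1] & ok[-length(ok)])
  if (length(hit) > 0) {
    list(reached = TRUE, session = hit[1] + 1L)
  } else {
    list(reached = FALSE, session = NA_integer_)
  }
}
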