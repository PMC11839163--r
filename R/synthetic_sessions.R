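#' Generate a synthetic CTTT session schedule and event log
#'
#' Builds one Cued-Triggered Turning Task session: 18 cue trials by default,
#' alternating turn and stop cues carried by tone or light with at most two
#' successive presentations of the same modality, intertrial intervals drawn
#' uniformly from 60 +/- 45 s, and a per-trial sampled outcome. Turn trials
#' yield a cued turn with probability `turn_prob`, with initiation drawn from
#' the phenotype's initiation-latency distribution (truncated to the 8-s
#' response bound) and completion following after a phenotype-specific turn
#' duration. Stop trials yield a cued stop with probability `stop_prob`,
#' otherwise a false turn during the 5-s treadmill pause. Cued turns and cued
#' stops are rewarded about 3.6 s (+/- 1 s jitter) after cue offset.
#'
#' @param config a [default_generator_config()] list.
#' @param phenotype phenotype label present in `config$phenotypes` (GT or ST).
#' @param seed integer seed; identical (config, phenotype, seed) give
#'   byte-identical sessions.
#' @param turn_cue_modality which cue modality signals a turn for this animal
#'   ("tone" or "light"); the stimulus-response mapping is counterbalanced
#'   across animals.
#' @return an object of class `cttt_session`: a list with `trials` (the event
#'   log data frame), `phenotype`, and `turn_cue_modality`.
#' @export
#' @examples
#' s <- gen_cttt_session(default_generator_config(), "GT", seed = 1)
#' nrow(s$trials)
gen_cttt_session <- function(config = default_generator_config(),
                             phenotype = "GT",
                             seed = 1,
                             turn_cue_modality = c("tone", "light")) {
  validate_generator_config(config)
  turn_cue_modality <- match.arg(turn_cue_modality)
  params <- phenotype_params(config, phenotype)

  withr::with_seed(seed, {
    n <- config$n_trials
    modality <- sample_modality_sequence(n)
    role <- ifelse(modality == turn_cue_modality, "turn", "stop")

    iti <- runif(n, config$iti_range[1], config$iti_range[2])
    block <- config$cue_duration + config$stop_delay + config$pause_duration
    cue_onset <- numeric(n)
    t_cursor <- 0
    for (i in seq_len(n)) {
      cue_onset[i] <- t_cursor + iti[i]
      t_cursor <- cue_onset[i] + block
    }
    cue_offset <- cue_onset + config$cue_duration
    treadmill_stop <- cue_offset + config$stop_delay
    pause_end <- treadmill_stop + config$pause_duration

    outcome <- character(n)
    turn_init <- rep(NA_real_, n)
    turn_complete <- rep(NA_real_, n)
    reward <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (role[i] == "turn") {
        if (runif(1) < params$turn_prob) {
          outcome[i] <- "cued_turn"
          init <- rtruncnorm(1, params$turn_initiation_mean,
                             params$turn_initiation_sd, 0.2, 8)
          dur <- rtruncnorm(1, params$turn_duration_mean,
                            params$turn_duration_sd, 0.5, Inf)
          turn_init[i] <- cue_onset[i] + init
          turn_complete[i] <- turn_init[i] + dur
          reward[i] <- cue_offset[i] +
            runif(1, config$reward_delay_mean - config$reward_delay_jitter,
                  config$reward_delay_mean + config$reward_delay_jitter)
        } else {
          outcome[i] <- "miss"
        }
      } else {
        if (runif(1) < params$stop_prob) {
          outcome[i] <- "cued_stop"
          reward[i] <- cue_offset[i] +
            runif(1, config$reward_delay_mean - config$reward_delay_jitter,
                  config$reward_delay_mean + config$reward_delay_jitter)
        } else {
          outcome[i] <- "false_turn"
          turn_init[i] <- runif(1, treadmill_stop[i], pause_end[i])
          turn_complete[i] <- turn_init[i] +
            rtruncnorm(1, params$turn_duration_mean,
                       params$turn_duration_sd, 0.5, Inf)
        }
      }
    }

    trials <- data.frame(
      trial = seq_len(n),
      modality = modality,
      role = role,
      cue_onset_s = cue_onset,
      cue_offset_s = cue_offset,
      treadmill_stop_s = treadmill_stop,
      pause_end_s = pause_end,
      outcome = outcome,
      turn_init_s = turn_init,
      turn_complete_s = turn_complete,
      reward_s = reward,
      stringsAsFactors = FALSE
    )
    structure(list(trials = trials,
                   phenotype = phenotype,
                   turn_cue_modality = turn_cue_modality),
              class = "cttt_session")
  })
}

# Balanced tone/light sequence with no run of three equal modalities,
# by rejection sampling of balanced permutations.
sample_modality_sequence <- function(n) {
  n_tone <- ceiling(n / 2)
  base <- c(rep("tone", n_tone), rep("light", n - n_tone))
  for (attempt in seq_len(10000)) {
    seq <- sample(base)
    r <- rle(seq)
    if (max(r$lengths) <= 2) {
      return(seq)
    }
  }
  stop("failed to draw a cue-modality sequence without triple repeats")
}

#' @export
print.cttt_session <- function(x, ...) {
  cat(sprintf("CTTT session (%s): %d trials (%d turn cues, %d stop cues)\n",
              x$phenotype, nrow(x$trials),
              sum(x$trials$role == "turn"), sum(x$trials$role == "stop")))
  counts <- table(x$trials$outcome)
  cat("outcomes:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' Generate synthetic PCA training sessions
#'
#' Produces Pavlovian Conditioned Approach trial records: 25 trials per
#' session, each with lever-contact and food-port-entry counts and first
#' latencies during the 8-s CS period, plus intertrial-interval port entries.
#' Stochastic phenotype presets draw trial behavior from phenotype-dependent
#' distributions; the deterministic extremes `"pure_ST"` (a lever contact at
#' CS onset on every trial, no CS-period port entries) and `"pure_GT"` (a
#' port entry at CS onset on every trial, no lever contacts) pin the PCA
#' index at exactly +1 and -1.
#'
#' @param phenotype one of "GT", "ST", "IN", "pure_GT", "pure_ST".
#' @param n_sessions number of sessions (>= 1); phenotype classification uses
#'   sessions 4 and 5, so the default is 5.
#' @param seed integer seed.
#' @param n_trials trials per session (default 25).
#' @param rat_id identifier copied into the records.
#' @return a data frame of trial records with columns `rat_id`, `session`,
#'   `trial`, `lever_contacts`, `lever_latency_s`, `cs_port_entries`,
#'   `port_latency_s`, `iti_port_entries`.
#' @export
gen_pca_sessions <- function(phenotype = c("GT", "ST", "IN", "pure_GT", "pure_ST"),
                             n_sessions = 5,
                             seed = 1,
                             n_trials = 25,
                             rat_id = "rat01") {
  phenotype <- match.arg(phenotype)
  if (!is_scalar_number(n_sessions) || n_sessions < 1) {
    stop("n_sessions must be >= 1", call. = FALSE)
  }
  n_sessions <- as.integer(n_sessions)

  if (phenotype %in% c("pure_GT", "pure_ST")) {
    lever <- phenotype == "pure_ST"
    out <- expand.grid(trial = seq_len(n_trials), session = seq_len(n_sessions))
    df <- data.frame(
      rat_id = rat_id,
      session = out$session,
      trial = out$trial,
      lever_contacts = if (lever) 1L else 0L,
      lever_latency_s = if (lever) 0 else NA_real_,
      cs_port_entries = if (lever) 0L else 1L,
      port_latency_s = if (lever) NA_real_ else 0,
      iti_port_entries = 0L,
      stringsAsFactors = FALSE
    )
    return(df)
  }

  # stochastic presets: per-trial response probabilities and latency laws
  presets <- list(
    GT = list(p_lever = 0.08, lever_n = 1.2, lever_lat = c(5.0, 2.0),
              p_port = 0.92, port_n = 2.0, port_lat = c(1.5, 1.0),
              iti_rate = 3),
    ST = list(p_lever = 0.92, lever_n = 2.5, lever_lat = c(1.5, 1.0),
              p_port = 0.10, port_n = 1.2, port_lat = c(5.0, 2.0),
              iti_rate = 1.5),
    IN = list(p_lever = 0.5, lever_n = 1.5, lever_lat = c(3.5, 2.0),
              p_port = 0.5, port_n = 1.5, port_lat = c(3.5, 2.0),
              iti_rate = 2)
  )
  p <- presets[[phenotype]]

  withr::with_seed(seed, {
    rows <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      lever_hit <- runif(n_trials) < p$p_lever
      port_hit <- runif(n_trials) < p$p_port
      lever_contacts <- ifelse(lever_hit, 1L + rpois(n_trials, p$lever_n - 1), 0L)
      cs_port_entries <- ifelse(port_hit, 1L + rpois(n_trials, p$port_n - 1), 0L)
      lever_latency <- ifelse(lever_hit,
                              rtruncnorm(n_trials, p$lever_lat[1], p$lever_lat[2], 0, 8),
                              NA_real_)
      port_latency <- ifelse(port_hit,
                             rtruncnorm(n_trials, p$port_lat[1], p$port_lat[2], 0, 8),
                             NA_real_)
      rows[[s]] <- data.frame(
        rat_id = rat_id,
        session = s,
        trial = seq_len(n_trials),
        lever_contacts = as.integer(lever_contacts),
        lever_latency_s = lever_latency,
        cs_port_entries = as.integer(cs_port_entries),
        port_latency_s = port_latency,
        iti_port_entries = rpois(n_trials, p$iti_rate),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}
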