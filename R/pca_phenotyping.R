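#' Aggregate PCA trial records into session measures
#'
#' Collapses per-trial Pavlovian Conditioned Approach records into the five
#' session measures: lever contacts, latency to first lever contact, CS-period
#' food-port entries, latency to first port entry, and intertrial-interval
#' port entries. Trials without a response of a kind contribute the CS
#' duration (8 s) as that kind's latency, the cap convention that pins the
#' index at exactly +/-1 for pure sign-/goal-tracking sessions.
#'
#' @param trials data frame with one row per trial: `lever_contacts`,
#'   `lever_latency_s` (`NA` when no contact), `cs_port_entries`,
#'   `port_latency_s` (`NA` when no entry), `iti_port_entries`.
#' @param cs_duration CS (lever presentation) duration in s.
#' @return a list of class `pca_session_measures`.
#' @export
session_measures <- function(trials, cs_duration = 8) {
  needed <- c("lever_contacts", "lever_latency_s", "cs_port_entries",
              "port_latency_s")
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("trials must be a non-empty data frame", call. = FALSE)
  }
  if (!all(needed %in% names(trials))) {
    stop("trials is missing columns: ",
         paste(setdiff(needed, names(trials)), collapse = ", "), call. = FALSE)
  }
  lat <- c(trials$lever_latency_s, trials$port_latency_s)
  if (any(lat < 0 | lat > cs_duration, na.rm = TRUE)) {
    stop(sprintf("latencies must lie in [0, %g] s", cs_duration), call. = FALSE)
  }
  cap <- function(latency, responded) {
    ifelse(responded & !is.na(latency), latency, cs_duration)
  }
  lever_resp <- trials$lever_contacts >= 1
  port_resp <- trials$cs_port_entries >= 1
  structure(list(
    n_trials = nrow(trials),
    lever_contacts = sum(trials$lever_contacts),
    lever_trials = sum(lever_resp),
    lever_latency_mean = mean(cap(trials$lever_latency_s, lever_resp)),
    cs_port_entries = sum(trials$cs_port_entries),
    port_trials = sum(port_resp),
    port_latency_mean = mean(cap(trials$port_latency_s, port_resp)),
    iti_port_entries = if ("iti_port_entries" %in% names(trials)) {
      sum(trials$iti_port_entries)
    } else {
      NA_integer_
    },
    cs_duration = cs_duration
  ), class = "pca_session_measures")
}

#' Compute the PCA index
#'
#' Combines three session measures into the Pavlovian Conditioned Approach
#' index of sign- versus goal-tracking:
#' probability difference `P(lever) - P(food port)`, response bias
#' `(lever contacts - port entries) / (lever contacts + port entries)`
#' (defined as 0 when no CS-period response of either kind occurred), and
#' latency score `(port latency - lever latency) / 8`. The index is the mean
#' of the three components; each lies in `[-1, +1]`, with +1 a lever
#' (sign-tracking) response on every trial and -1 a food-port
#' (goal-tracking) response on every trial. The classification basis is the
#' index averaged over sessions 4 and 5.
#'
#' @param measures a `pca_session_measures`, or a list of them (optionally
#'   named by session number).
#' @param sessions session numbers averaged for the classification basis.
#' @return for a single session, a list of class `pca_index` with
#'   `prob_diff`, `resp_bias`, `latency_score`, `index`; for several, that
#'   per-session list plus `average` over `sessions` (error if absent).
#' @export
#' @examples
#' m <- session_measures(data.frame(
#'   lever_contacts = 1, lever_latency_s = 0,
#'   cs_port_entries = 0, port_latency_s = NA, iti_port_entries = 0
#' ))
#' compute_pca_index(m)$index # +1
compute_pca_index <- function(measures, sessions = c(4, 5)) {
  one <- function(m) {
    stopifnot(inherits(m, "pca_session_measures"))
    prob_diff <- m$lever_trials / m$n_trials - m$port_trials / m$n_trials
    total <- m$lever_contacts + m$cs_port_entries
    resp_bias <- if (total == 0) 0 else (m$lever_contacts - m$cs_port_entries) / total
    latency_score <- (m$port_latency_mean - m$lever_latency_mean) / m$cs_duration
    structure(list(prob_diff = prob_diff, resp_bias = resp_bias,
                   latency_score = latency_score,
                   index = mean(c(prob_diff, resp_bias, latency_score))),
              class = "pca_index")
  }
  if (inherits(measures, "pca_session_measures")) {
    return(one(measures))
  }
  per_session <- lapply(measures, one)
  ids <- names(measures)
  ids <- if (is.null(ids) || any(ids == "")) seq_along(measures) else as.numeric(ids)
  if (!all(sessions %in% ids)) {
    stop("requested sessions absent: ",
         paste(setdiff(sessions, ids), collapse = ", "), call. = FALSE)
  }
  avg <- mean(vapply(per_session[match(sessions, ids)], `[[`, numeric(1), "index"))
  list(per_session = per_session, session_ids = ids, average = avg)
}

#' Classify a phenotype from the averaged PCA index
#'
#' Averaged indices in `[-1.0, -0.5]` are goal-trackers (GT), in
#' `[+0.5, +1.0]` sign-trackers (ST), and the interior band intermediates
#' (IN); the boundary values +/-0.5 are assigned to GT/ST (inclusive).
#'
#' @param avg_index averaged PCA index in `[-1, 1]`.
#' @return `"GT"`, `"IN"`, or `"ST"`.
#' @export
classify_phenotype <- function(avg_index) {
  if (!is_scalar_number(avg_index) || avg_index < -1 || avg_index > 1) {
    stop("avg_index must lie in [-1, 1]", call. = FALSE)
  }
  if (avg_index <= -0.5) {
    "GT"
  } else if (avg_index >= 0.5) {
    "ST"
  } else {
    "IN"
  }
}

#' Score a full PCA trial file: per-session indices and phenotype per rat
#'
#' @param trials trial records for one or more rats
#'   (see [gen_pca_sessions()] for the columns).
#' @param sessions sessions averaged for classification.
#' @return a data frame with one row per rat x session (components and
#'   index) plus attribute `"labels"`: per-rat averaged index and label.
#' @export
score_pca <- function(trials, sessions = c(4, 5)) {
  stopifnot("rat_id" %in% names(trials), "session" %in% names(trials))
  rows <- list()
  labels <- list()
  for (rat in unique(trials$rat_id)) {
    sub <- trials[trials$rat_id == rat, , drop = FALSE]
    ids <- sort(unique(sub$session))
    ms <- lapply(ids, function(s) {
      session_measures(sub[sub$session == s, , drop = FALSE])
    })
    names(ms) <- ids
    res <- compute_pca_index(ms, sessions = sessions)
    for (k in seq_along(ids)) {
      idx <- res$per_session[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        rat_id = rat, session = ids[k],
        prob_diff = idx$prob_diff, resp_bias = idx$resp_bias,
        latency_score = idx$latency_score, index = idx$index,
        stringsAsFactors = FALSE)
    }
    labels[[length(labels) + 1]] <- data.frame(
      rat_id = rat, avg_index = res$average,
      label = classify_phenotype(res$average), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- do.call(rbind, labels)
  out
}
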