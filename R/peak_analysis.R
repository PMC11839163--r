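#' Detect glutamate peaks in an event-locked window
#'
#' Implements the three-criterion peak definition used for cue- and
#' reward-locked transients:
#'
#' 1. a peak must exceed the average baseline by more than 3 baseline SDs;
#' 2. the signal must drop to at least 1 baseline SD below the peak value on
#'    both sides, before rising above it (the pre-window side is treated as
#'    baseline-level and therefore satisfies the drop for the first peak;
#'    the window end likewise satisfies the drop for a trailing peak);
#' 3. a maximal run of consecutive supra-threshold samples that contains no
#'    peak by criterion 2 and whose values lie within 1 SD of each other
#'    (range < 1 SD) contributes its highest sample as a single peak;
#'    without this rescue, sustained elevations would contribute no peak at
#'    all, while fluctuating elevations would not escalate the count.
#'
#' Criterion 2 is evaluated by an alternating max/min scan with drop
#' tolerance 1 SD (the classic `peakdet` scheme), initialized at baseline
#' level. Ties at equal maxima resolve to the earliest sample; apexes are
#' sample-aligned (no sub-sample interpolation at 5 Hz). Boundary cases use
#' strict `>` for the 3-SD threshold and `<=` for the 1-SD drops, resolving
#' toward fewer peaks.
#'
#' @param window numeric vector of glutamate concentrations (uM), typically
#'   baseline-corrected; must be non-empty.
#' @param baseline list with `mean` and `sd` (uM) of the trial's baseline
#'   window (`sd` must be > 0); for baseline-corrected windows `mean = 0`.
#' @param sampling_rate Hz, used to report apex times.
#' @return an object of class `peak_set`: a data frame with columns `index`,
#'   `apex_time_rel` (s from the window anchor), `concentration` (uM) and
#'   `rule_used` (`"prominence"` or `"adjacent_run"`), ordered by time.
#' @export
#' @examples
#' detect_peaks(c(0, 0.5, 4, 0.5, 0), baseline = list(mean = 0, sd = 1))
detect_peaks <- function(window, baseline, sampling_rate = 5) {
  if (length(window) == 0) stop("window is empty", call. = FALSE)
  if (!is_scalar_number(baseline$sd) || baseline$sd <= 0) {
    stop("baseline sd must be > 0", call. = FALSE)
  }
  m <- baseline$mean
  s <- baseline$sd
  theta <- m + 3 * s
  n <- length(window)

  # criterion 1+2: alternating max/min scan with drop tolerance 1 SD
  peaks_idx <- integer(0)
  mx <- -Inf
  mxpos <- NA_integer_
  mn <- m # pre-window treated as baseline-level
  lookformax <- FALSE
  for (i in seq_len(n)) {
    v <- window[i]
    if (lookformax) {
      if (v > mx) {
        mx <- v
        mxpos <- i
      } else if (v <= mx - s) {
        if (mx > theta) peaks_idx <- c(peaks_idx, mxpos)
        mn <- v
        lookformax <- FALSE
      }
    } else {
      if (v < mn) mn <- v
      if (v >= mn + s) {
        mx <- v
        mxpos <- i
        lookformax <- TRUE
      }
    }
  }
  if (lookformax && mx > theta) peaks_idx <- c(peaks_idx, mxpos) # edge drop

  rule <- rep("prominence", length(peaks_idx))

  # criterion 3: supra-threshold runs without a criterion-2 peak
  above <- window > theta
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      if (any(peaks_idx %in% idx)) next
      if (diff(range(window[idx])) < s) {
        top <- idx[which.max(window[idx])]
        peaks_idx <- c(peaks_idx, top)
        rule <- c(rule, "adjacent_run")
      }
    }
  }

  ord <- order(peaks_idx)
  out <- data.frame(
    index = peaks_idx[ord],
    apex_time_rel = (peaks_idx[ord] - 1) / sampling_rate,
    concentration = window[peaks_idx[ord]],
    rule_used = rule[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("peak_set", class(out))
  out
}

#' Summarize a peak set into trace-level features
#'
#' Extracts the maximum peak concentration, the number of peaks, and the
#' time to the maximum peak (from the window anchor: cue onset or reward
#' delivery). Traces without any identified peak yield missing markers,
#' never zero-filled values.
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @return a one-row data frame with `max_peak` (uM or `NA`), `n_peaks`,
#'   `time_to_max` (s or `NA`), and `second_peak_time` (apex time of the
#'   second peak, `NA` when fewer than two peaks).
#' @export
peak_features <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  n <- nrow(peaks)
  if (n == 0) {
    return(data.frame(max_peak = NA_real_, n_peaks = 0L,
                      time_to_max = NA_real_, second_peak_time = NA_real_))
  }
  imax <- which.max(peaks$concentration)
  data.frame(
    max_peak = peaks$concentration[imax],
    n_peaks = n,
    time_to_max = peaks$apex_time_rel[imax],
    second_peak_time = if (n >= 2) peaks$apex_time_rel[2] else NA_real_
  )
}

#' Peak features for every event window of a window set
#'
#' Runs [detect_peaks()] and [peak_features()] on each cue and reward window
#' of an [extract_windows()] result.
#'
#' @param windows an `event_window_set`.
#' @param kinds which window kinds to analyze.
#' @return a data frame with one row per (trial, window kind): `trial`,
#'   `event_kind`, `max_peak`, `n_peaks`, `time_to_max`, `second_peak_time`.
#' @export
window_peak_features <- function(windows, kinds = c("cue", "reward")) {
  fs <- attr(windows, "sampling_rate") %||% 5
  df <- as.data.frame(windows)
  df <- df[df$window %in% kinds, , drop = FALSE]
  keys <- unique(df[, c("trial", "window")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- df$trial == keys$trial[i] & df$window == keys$window[i]
    w <- df[sel, , drop = FALSE]
    w <- w[order(w$sample), , drop = FALSE]
    pk <- detect_peaks(w$glutamate_uM,
                       baseline = list(mean = 0, sd = w$baseline_sd[1]),
                       sampling_rate = fs)
    # report apex times relative to the true event anchor, not the grid
    pk$apex_time_rel <- w$t_rel_s[pk$index]
    rows[[i]] <- cbind(data.frame(trial = keys$trial[i],
                                  event_kind = keys$window[i],
                                  stringsAsFactors = FALSE),
                       peak_features(pk))
  }
  do.call(rbind, rows)
}

#' Tabulate peak-count frequencies by phenotype
#'
#' Counts traces with one, two, or three-or-more peaks per phenotype,
#' excluding zero-peak traces (tallied separately), for the chi-square
#' comparison of single- versus multi-peak prevalence between phenotypes.
#'
#' @param features data frame with columns `phenotype` and `n_peaks`.
#' @return a phenotype x category (`"1"`, `"2"`, `"3+"`) count matrix with
#'   attribute `"zero_peak"` giving per-phenotype zero-peak trace counts.
#' @export
classify_peak_count <- function(features) {
  stopifnot(all(c("phenotype", "n_peaks") %in% names(features)))
  nonzero <- features[features$n_peaks >= 1, , drop = FALSE]
  cat_lab <- cut(nonzero$n_peaks, breaks = c(0.5, 1.5, 2.5, Inf),
                 labels = c("1", "2", "3+"))
  tab <- table(phenotype = nonzero$phenotype, peaks = cat_lab)
  zero <- table(features$phenotype[features$n_peaks == 0])
  attr(tab, "zero_peak") <- zero
  tab
}
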