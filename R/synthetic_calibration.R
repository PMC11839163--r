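default_addition_schedule <- function() {
  data.frame(
    analyte = c("AA", "glutamate", "glutamate", "glutamate", "dopamine"),
    final_concentration = c(250, 20, 40, 60, 2),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic in-vitro calibration series
#'
#' Emulates the beaker calibration of a glutamate biosensor: a baseline
#' segment followed by sequential additions of ascorbic acid (AA, 250 uM),
#' glutamate to 20/40/60 uM cumulative, and dopamine (2 uM). The active
#' channel steps by `sensitivity x concentration` for glutamate, by
#' `sensitivity / aa_selectivity x concentration` for AA, and by
#' `da_response` for dopamine; the sentinel channel responds only to AA and
#' dopamine per the configured selectivities (the exclusion layer blocks AA
#' completely by default). Steps approach their plateau exponentially with
#' time constant `response_tau` and carry additive Gaussian noise.
#'
#' @param electrode list with `sensitivity` (pA/uM), `aa_selectivity`
#'   (glutamate:AA ratio), `da_response` (pA); see
#'   [default_generator_config()]`$electrode`.
#' @param noise_sd per-sample current noise SD in pA. The default 1.2 pA
#'   yields a 3 sd / slope limit of detection of 0.3 uM at 12 pA/uM.
#' @param seed integer seed.
#' @param additions addition schedule (analyte, final cumulative
#'   concentration in uM), in order of addition.
#' @param baseline_duration baseline segment length in s.
#' @param addition_interval time between additions in s.
#' @param sampling_rate Hz.
#' @param response_tau plateau approach time constant in s.
#' @param sentinel_aa_response sentinel AA sensitivity in pA/uM (default 0).
#' @return an object of class `calibration_series`: list with `time`,
#'   `active`, `sentinel` (currents in pA) and the timed `additions` table.
#' @export
#' @examples
#' s <- gen_calibration_series(noise_sd = 0, seed = 1)
#' fit_calibration(s)
gen_calibration_series <- function(electrode = default_generator_config()$electrode,
                                   noise_sd = 1.2,
                                   seed = 1,
                                   additions = default_addition_schedule(),
                                   baseline_duration = 60,
                                   addition_interval = 60,
                                   sampling_rate = 5,
                                   response_tau = 1.5,
                                   sentinel_aa_response = 0) {
  if (!is_scalar_number(electrode$sensitivity) || electrode$sensitivity < 0) {
    stop("electrode sensitivity must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(nrow(additions) >= 1)

  additions$time <- baseline_duration +
    (seq_len(nrow(additions)) - 1) * addition_interval
  duration <- baseline_duration + nrow(additions) * addition_interval
  n <- floor(duration * sampling_rate) + 1
  time <- (seq_len(n) - 1) / sampling_rate

  aa_sens <- if (electrode$aa_selectivity > 0) {
    electrode$sensitivity / electrode$aa_selectivity
  } else {
    0
  }

  # per-addition plateau step on each channel (pA)
  step_for <- function(analyte, conc_step, channel) {
    if (analyte == "glutamate") {
      if (channel == "active") electrode$sensitivity * conc_step else 0
    } else if (analyte == "AA") {
      if (channel == "active") aa_sens * conc_step else sentinel_aa_response * conc_step
    } else if (analyte == "dopamine") {
      electrode$da_response # both channels respond to dopamine
    } else {
      stop(sprintf("unknown analyte '%s'", analyte), call. = FALSE)
    }
  }

  withr::with_seed(seed, {
    active <- rep(100, n)   # standing baseline current, pA
    sentinel <- rep(100, n)
    prev_conc <- list(glutamate = 0, AA = 0, dopamine = 0)
    for (i in seq_len(nrow(additions))) {
      an <- additions$analyte[i]
      conc_step <- additions$final_concentration[i] - prev_conc[[an]]
      prev_conc[[an]] <- additions$final_concentration[i]
      rel <- time - additions$time[i]
      approach <- ifelse(rel < 0, 0, 1 - exp(-rel / response_tau))
      active <- active + step_for(an, conc_step, "active") * approach
      sentinel <- sentinel + step_for(an, conc_step, "sentinel") * approach
    }
    if (noise_sd > 0) {
      active <- active + rnorm(n, 0, noise_sd)
      sentinel <- sentinel + rnorm(n, 0, noise_sd)
    }
    structure(list(time = time, active = active, sentinel = sentinel,
                   additions = additions),
              class = "calibration_series")
  })
}

#' @export
print.calibration_series <- function(x, ...) {
  cat(sprintf("calibration series: %d samples, %d additions (%s)\n",
              length(x$time), nrow(x$additions),
              paste(unique(x$additions$analyte), collapse = ", ")))
  invisible(x)
}

#' Write / read a calibration series as CSV
#'
#' Samples go to `path` (`time_s`, `active_pA`, `sentinel_pA`); the addition
#' log goes to the same path with suffix `_additions.csv`.
#'
#' @param series a `calibration_series`.
#' @param path CSV file path.
#' @return the path / the series.
#' @export
write_calibration_csv <- function(series, path) {
  write.csv(data.frame(time_s = series$time,
                       active_pA = series$active,
                       sentinel_pA = series$sentinel),
            path, row.names = FALSE)
  write.csv(series$additions, sub("\\.csv$", "_additions.csv", path),
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  additions <- read.csv(sub("\\.csv$", "_additions.csv", path),
                        stringsAsFactors = FALSE)
  structure(list(time = df$time_s, active = df$active_pA,
                 sentinel = df$sentinel_pA, additions = additions),
            class = "calibration_series")
}
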