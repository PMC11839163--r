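#' Fit an in-vitro calibration series
#'
#' Estimates the per-electrode calibration characteristics from a
#' `calibration_series`: sensitivity (intercept-free least-squares slope of
#' plateau current change versus cumulative glutamate concentration,
#' referenced to the plateau immediately preceding the first glutamate
#' addition), linearity (correlation of plateau change vs concentration, R,
#' with R^2 also reported), limit of detection (3 x baseline current SD /
#' sensitivity), glutamate:AA selectivity (sensitivity divided by the AA
#' plateau shift per uM AA), and the dopamine response (active-channel
#' plateau shift after the dopamine addition). Plateaus are estimated as the
#' mean of the last `plateau_window` seconds of each addition segment.
#'
#' @param series a `calibration_series` (see [gen_calibration_series()] /
#'   [read_calibration_csv()]).
#' @param plateau_window seconds of settled signal averaged per plateau.
#' @param criteria acceptance criteria, see [evaluate_criteria()].
#' @return an object of class `calibration_result` with fields `sensitivity`
#'   (pA/uM), `linearity_r`, `linearity_r2`, `lod` (uM), `selectivity`,
#'   `da_response` (pA), `baseline_sd` (pA), and `passed` (per-criterion
#'   flags plus `overall`). Selectivity is `Inf` (flagged via
#'   `aa_response_zero`) when the AA plateau shift is not positive.
#' @export
#' @examples
#' fit_calibration(gen_calibration_series(noise_sd = 0, seed = 1))
fit_calibration <- function(series, plateau_window = 10,
                            criteria = default_calibration_criteria()) {
  stopifnot(inherits(series, "calibration_series") ||
              (is.list(series) && !is.null(series$additions)))
  additions <- series$additions
  if (is.unsorted(additions$time, strictly = TRUE)) {
    stop("additions must be strictly increasing in time", call. = FALSE)
  }
  glu <- additions[additions$analyte == "glutamate", , drop = FALSE]
  if (nrow(glu) == 0) {
    stop("calibration series contains no glutamate additions", call. = FALSE)
  }
  if (nrow(glu) >= 2 && is.unsorted(glu$final_concentration, strictly = TRUE)) {
    stop("glutamate additions must be strictly increasing in concentration",
         call. = FALSE)
  }
  if (min(additions$time) <= 0) {
    stop("series must contain a pre-addition baseline segment", call. = FALSE)
  }

  time <- series$time
  active <- series$active
  bounds <- c(additions$time, max(time) + 1e-9)

  plateau <- function(seg_start, seg_end) {
    sel <- time >= max(seg_start, seg_end - plateau_window) & time < seg_end
    mean(active[sel])
  }
  seg_plateau <- function(i) plateau(bounds[i], bounds[i + 1]) # i-th addition

  baseline_sel <- time < additions$time[1]
  baseline_level <- plateau(0, additions$time[1])
  baseline_sd <- sd(active[baseline_sel])

  # reference for glutamate shifts: plateau immediately before the first
  # glutamate addition (baseline, or the AA plateau when AA precedes)
  first_glu <- match("glutamate", additions$analyte)
  glu_ref <- if (first_glu == 1) baseline_level else seg_plateau(first_glu - 1)

  glu_idx <- which(additions$analyte == "glutamate")
  shifts <- vapply(glu_idx, seg_plateau, numeric(1)) - glu_ref
  conc <- additions$final_concentration[glu_idx]

  sensitivity <- sum(shifts * conc) / sum(conc^2) # intercept-free LS slope
  linearity_r <- if (length(conc) >= 2 && sd(shifts) > 0) cor(shifts, conc) else NA_real_
  if (length(conc) >= 2 && sd(shifts) == 0) linearity_r <- 0

  aa_idx <- which(additions$analyte == "AA")
  if (length(aa_idx) > 0) {
    i <- aa_idx[1]
    aa_ref <- if (i == 1) baseline_level else seg_plateau(i - 1)
    aa_shift <- seg_plateau(i) - aa_ref
    aa_sens <- aa_shift / additions$final_concentration[i]
  } else {
    aa_shift <- NA_real_
    aa_sens <- NA_real_
  }
  aa_zero <- !is.na(aa_sens) && aa_sens <= 0
  selectivity <- if (is.na(aa_sens)) {
    NA_real_
  } else if (aa_zero) {
    Inf
  } else {
    sensitivity / aa_sens
  }

  da_idx <- which(additions$analyte == "dopamine")
  da_response <- if (length(da_idx) > 0) {
    i <- da_idx[1]
    da_ref <- if (i == 1) baseline_level else seg_plateau(i - 1)
    seg_plateau(i) - da_ref
  } else {
    NA_real_
  }

  lod <- if (sensitivity > 0) 3 * baseline_sd / sensitivity else Inf

  result <- structure(list(
    sensitivity = sensitivity,
    linearity_r = linearity_r,
    linearity_r2 = if (is.na(linearity_r)) NA_real_ else linearity_r^2,
    lod = lod,
    selectivity = selectivity,
    da_response = da_response,
    baseline_sd = baseline_sd,
    aa_response_zero = aa_zero,
    glutamate_concentrations = conc,
    plateau_shifts = shifts
  ), class = "calibration_result")
  result$passed <- evaluate_criteria(result, criteria)
  result
}

#' Acceptance criteria for glutamate biosensors
#'
#' The electrode acceptance thresholds: sensitivity above 5 pA/uM, limit of
#' detection below 1.0 uM, glutamate:AA selectivity above 50:1, dopamine
#' response strictly below 3 pA in magnitude, and linearity R above 0.95.
#'
#' @return a named list of thresholds.
#' @export
default_calibration_criteria <- function() {
  list(min_sensitivity = 5,    # pA/uM, strict >
       max_lod = 1.0,          # uM, strict <
       min_selectivity = 50,   # ratio, strict >
       max_da_response = 3,    # pA, strict <
       min_linearity_r = 0.95) # strict >
}

#' Evaluate electrode acceptance criteria
#'
#' @param result a `calibration_result` (all fields must be present).
#' @param criteria thresholds, see [default_calibration_criteria()].
#' @return named logical list with one flag per criterion and `overall`
#'   (their conjunction).
#' @export
evaluate_criteria <- function(result, criteria = default_calibration_criteria()) {
  needed <- c("sensitivity", "lod", "selectivity", "da_response", "linearity_r")
  vals <- result[needed]
  if (any(vapply(vals, function(v) is.null(v) || length(v) != 1 || is.na(v),
                 logical(1)))) {
    stop("calibration result is missing fields: ",
         paste(needed[vapply(vals, function(v) is.null(v) || length(v) != 1 || is.na(v),
                             logical(1))], collapse = ", "),
         call. = FALSE)
  }
  flags <- list(
    sensitivity = result$sensitivity > criteria$min_sensitivity,
    lod = result$lod < criteria$max_lod,
    selectivity = result$selectivity > criteria$min_selectivity &&
      !isTRUE(result$aa_response_zero),
    da_response = abs(result$da_response) < criteria$max_da_response,
    linearity = result$linearity_r > criteria$min_linearity_r
  )
  flags$overall <- all(unlist(flags))
  flags
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration result\n")
  cat(sprintf("  sensitivity : %8.2f pA/uM\n", x$sensitivity))
  cat(sprintf("  linearity R : %8.4f (R^2 = %.4f)\n", x$linearity_r, x$linearity_r2))
  cat(sprintf("  LOD         : %8.3f uM\n", x$lod))
  cat(sprintf("  selectivity : %8.1f : 1 (glutamate:AA)\n", x$selectivity))
  cat(sprintf("  DA response : %8.3f pA\n", x$da_response))
  status <- if (isTRUE(x$passed$overall)) "PASS" else "FAIL"
  failing <- names(x$passed)[!unlist(x$passed)]
  failing <- setdiff(failing, "overall")
  cat(sprintf("  criteria    : %s%s\n", status,
              if (length(failing)) paste0(" (failing: ", paste(failing, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Write a calibration result to JSON
#'
#' @param result a `calibration_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  out <- unclass(result)
  out$selectivity <- if (is.infinite(out$selectivity)) "Inf" else out$selectivity
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
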