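#' Construct a dual-channel amperometric trace
#'
#' A `dual_channel_trace` couples the current recorded at a glutamate
#' oxidase-coated ("active") site with the current at an enzyme-free
#' ("sentinel") site sampled on a common, uniform clock, plus electrode
#' metadata (identifier, sampling rate, dopamine response from the in-vitro
#' calibration, and quality-control flags).
#'
#' @param time sample times in seconds, strictly increasing and uniform.
#' @param active active-site current in pA.
#' @param sentinel sentinel-site current in pA.
#' @param metadata named list; `sampling_rate` is filled in from `time` when
#'   absent. QC flags (`artifact_detected`, `task_noncompliance`,
#'   `placement_rejected`) default to `FALSE`; they encode judgments external
#'   to the signal and are accepted as inputs.
#' @return an object of class `dual_channel_trace`.
#' @export
new_dual_channel_trace <- function(time, active, sentinel, metadata = list()) {
  if (length(active) != length(sentinel) || length(time) != length(active)) {
    stop("time, active and sentinel must have equal length", call. = FALSE)
  }
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9) {
      stop("time must be strictly increasing and uniform", call. = FALSE)
    }
  }
  if (is.null(metadata$sampling_rate)) {
    metadata$sampling_rate <- if (length(time) > 1) 1 / (time[2] - time[1]) else NA_real_
  }
  qc_defaults <- list(artifact_detected = FALSE,
                      task_noncompliance = FALSE,
                      placement_rejected = FALSE)
  metadata$qc <- modify_list_deep(qc_defaults, metadata$qc %||% list())
  structure(list(time = time, active = active, sentinel = sentinel,
                 metadata = metadata),
            class = "dual_channel_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dual_channel_trace <- function(x, ...) {
  cat(sprintf("dual-channel trace: %d samples at %.3g Hz (%.1f s)\n",
              length(x$time), x$metadata$sampling_rate,
              diff(range(x$time))))
  if (!is.null(x$metadata$electrode_id)) {
    cat("electrode:", x$metadata$electrode_id, "\n")
  }
  flags <- unlist(x$metadata$qc)
  if (any(flags)) cat("QC flags set:", paste(names(flags)[flags], collapse = ", "), "\n")
  invisible(x)
}

#' Drop traces failing quality-control flags
#'
#' Mirrors the study's trace-inclusion rules: traces flagged for electrostatic
#' artifacts, task non-compliance, or rejected electrode placement are removed
#' (the calibration criterion is enforced separately at conversion time).
#'
#' @param traces a list of `dual_channel_trace` objects.
#' @return the retained traces, with attribute `"excluded"` giving per-flag
#'   exclusion counts.
#' @export
filter_traces <- function(traces) {
  flags <- vapply(traces, function(tr) unlist(tr$metadata$qc), logical(3))
  drop <- apply(flags, 2, any)
  kept <- traces[!drop]
  attr(kept, "excluded") <- rowSums(flags[, drop, drop = FALSE])
  kept
}

#' Write / read a dual-channel trace as CSV plus JSON sidecar
#'
#' The CSV holds `time_s`, `active_pA`, `sentinel_pA`; the sidecar
#' (same path with extension `.json`) holds the metadata.
#'
#' @param trace a `dual_channel_trace`.
#' @param path CSV file path.
#' @return `write_trace_csv` the path, invisibly; `read_trace_csv` the trace.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time,
                   active_pA = trace$active,
                   sentinel_pA = trace$sentinel)
  write.csv(df, path, row.names = FALSE)
  meta <- trace$metadata
  meta$truth <- NULL # provenance of synthetic traces stays in memory
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(meta$qc)) meta$qc <- as.list(meta$qc)
  new_dual_channel_trace(df$time_s, df$active_pA, df$sentinel_pA, meta)
}
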