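#' Default phenotype parameters for the synthetic-data generator
#'
#' Returns the per-phenotype parameter block used by [gen_cttt_session()],
#' [gen_glutamate_trace()] and [gen_pca_sessions()]. Goal-trackers (GT) are
#' parameterized with predominately single, high-amplitude cue-locked
#' transients, later turn initiation, and a higher turn rate; sign-trackers
#' (ST) with mostly multi-peak (two or three), lower-amplitude cue-locked
#' transients whose second and third peaks occur 1.58 +/- 0.39 s and
#' 1.83 +/- 0.25 s after cue onset, earlier turn initiation, a lower turn
#' rate, and larger reward-locked transients.
#'
#' @param phenotype "GT" or "ST".
#' @return a named list of phenotype parameters.
#' @export
default_phenotype_params <- function(phenotype = c("GT", "ST")) {
  phenotype <- match.arg(phenotype)
  base <- list(
    # cue-locked transient structure
    single_peak_prob = 0.8,
    peak_amplitude_mean = 8.5,  # uM
    peak_amplitude_sd = 2.5,
    extra_peak_latency_means = c(1.58, 1.83), # s after cue onset (2nd, 3rd)
    extra_peak_latency_sds = c(0.39, 0.25),
    extra_peak_count_probs = c(0.6, 0.4),     # P(2 peaks), P(3 peaks) | multi
    extra_peak_amplitude_scale = 0.85,
    # reward-locked transients
    reward_peak_prob = 0.5,
    reward_peak_amplitude_mean = 4.0, # uM
    reward_peak_amplitude_sd = 1.5,
    # behavior
    turn_prob = 0.75,
    stop_prob = 0.85,
    turn_initiation_mean = 2.5, # s after cue onset
    turn_initiation_sd = 1.0,
    turn_duration_mean = 2.7,   # s, initiation -> completion
    turn_duration_sd = 0.5
  )
  if (phenotype == "ST") {
    base$single_peak_prob <- 0.2
    base$peak_amplitude_mean <- 5.5
    base$peak_amplitude_sd <- 2.0
    base$reward_peak_prob <- 0.9
    base$reward_peak_amplitude_mean <- 8.0
    base$reward_peak_amplitude_sd <- 2.0
    base$turn_prob <- 0.65
    base$turn_initiation_mean <- 1.5
    base$turn_initiation_sd <- 0.8
    base$turn_duration_mean <- 2.3
  }
  base
}

#' Default configuration of the synthetic-data generator
#'
#' Holds every knob of the synthetic recordings and behavioral sessions:
#' sampling rate (5 Hz), channel noise, shared drift and artifact injection,
#' the shape of glutamate transients (double-exponential pulse), trial
#' timeline constants of the turning task (2-s cue, treadmill stop 1 s after
#' cue offset, 5-s pause, 18 trials, intertrial intervals of 60 +/- 45 s,
#' reward about 3.6 s after cue offset), electrode constants (sensitivity,
#' glutamate:AA selectivity, dopamine response), and per-phenotype behavior
#' and peak-structure parameters (see [default_phenotype_params()]).
#'
#' @param sampling_rate sampling rate in Hz.
#' @param noise_sd per-channel baseline current noise SD in pA. The default,
#'   3.6 pA, corresponds to 0.3 uM at the default 12 pA/uM sensitivity.
#' @param drift_rate shared slow drift in pA/s.
#' @param artifact_rate rate of shared rectangular artifacts in events/min.
#' @return a list of class `generator_config`.
#' @export
default_generator_config <- function(sampling_rate = 5,
                                     noise_sd = 3.6,
                                     drift_rate = 0.005,
                                     artifact_rate = 0.2) {
  cfg <- list(
    sampling_rate = sampling_rate,
    noise_sd = noise_sd,
    drift_rate = drift_rate,
    baseline_current = 200,   # pA, common to both channels
    artifact_rate = artifact_rate,
    artifact_amplitude = 50,  # pA
    artifact_duration = 1.0,  # s
    # transient pulse shape (double exponential, normalized to unit apex)
    pulse_rise = 0.25,        # s
    pulse_decay = 0.45,       # s
    first_peak_latency_mean = 0.4, # s after cue onset (single-peak traces)
    first_peak_latency_sd = 0.1,
    first_peak_latency_range = c(0.2, 0.7),
    # first peak of multi-peak traces sits earlier, leaving room for the
    # second/third transients inside the cue-locked analysis window
    multi_first_peak_latency_mean = 0.3,
    multi_first_peak_latency_sd = 0.08,
    multi_first_peak_latency_range = c(0.2, 0.5),
    min_peak_separation = 0.5, # s, below this two transients merge at 5 Hz
    # CTTT trial timeline
    n_trials = 18,
    cue_duration = 2,
    stop_delay = 1,           # s after cue offset
    pause_duration = 5,
    iti_range = c(15, 105),   # s, uniform (60 +/- 45 s)
    reward_delay_mean = 3.6,  # s after cue offset
    reward_delay_jitter = 1.0,
    trial_tail = 15,          # s of trace retained after the last event
    # electrode constants
    electrode = list(
      sensitivity = 12.0,     # pA/uM
      aa_selectivity = 113.1, # glutamate:AA sensitivity ratio
      da_response = 0.05      # pA evoked by 2 uM dopamine
    ),
    phenotypes = list(
      GT = default_phenotype_params("GT"),
      ST = default_phenotype_params("ST")
    )
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' @param config a `generator_config` list.
#' @return the config, invisibly usable; errors on invalid fields.
#' @export
validate_generator_config <- function(config) {
  stopifnot(is.list(config))
  if (!is_scalar_number(config$sampling_rate) || config$sampling_rate <= 0) {
    stop("sampling_rate must be a positive number", call. = FALSE)
  }
  if (!is_scalar_number(config$noise_sd) || config$noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (config$pulse_decay <= config$pulse_rise) {
    stop("pulse_decay must exceed pulse_rise", call. = FALSE)
  }
  if (config$electrode$sensitivity < 0) {
    stop("electrode sensitivity must be >= 0", call. = FALSE)
  }
  for (ph in names(config$phenotypes)) {
    p <- config$phenotypes[[ph]]
    stop_if_not_prob(p$single_peak_prob, paste0(ph, "$single_peak_prob"))
    stop_if_not_prob(p$turn_prob, paste0(ph, "$turn_prob"))
    stop_if_not_prob(p$stop_prob, paste0(ph, "$stop_prob"))
    stop_if_not_prob(p$reward_peak_prob, paste0(ph, "$reward_peak_prob"))
    if (abs(sum(p$extra_peak_count_probs) - 1) > 1e-8) {
      stop(sprintf("%s$extra_peak_count_probs must sum to 1", ph), call. = FALSE)
    }
    if (length(p$extra_peak_latency_means) != length(p$extra_peak_latency_sds)) {
      stop("extra peak latency means and sds must have equal length", call. = FALSE)
    }
  }
  invisible(config)
}

phenotype_params <- function(config, phenotype) {
  p <- config$phenotypes[[phenotype]]
  if (is.null(p)) {
    stop(sprintf("unknown phenotype label '%s' (configured: %s)",
                 phenotype, paste(names(config$phenotypes), collapse = ", ")),
         call. = FALSE)
  }
  p
}

#' Read a generator/run configuration from a YAML or JSON document
#'
#' The document mirrors the structure of [default_generator_config()] (or of
#' [default_run_config()] when `kind = "run"`); fields present in the file
#' override defaults, fields absent keep their default value.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param kind `"generator"` or `"run"`.
#' @return a validated configuration list.
#' @export
read_config <- function(path, kind = c("generator", "run")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml, .yml or .json file", call. = FALSE)
  }
  defaults <- if (kind == "generator") default_generator_config() else default_run_config()
  merged <- modify_list_deep(defaults, doc)
  if (kind == "generator") {
    class(merged) <- "generator_config"
    validate_generator_config(merged)
  } else {
    validate_run_config(merged)
  }
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
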