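#' Derive a child seed from a run seed and a stage label
#'
#' Fans a single run seed out to per-stage seeds by a stable string hash, so
#' that individual pipeline stages can be rerun independently while remaining
#' deterministic for a given (seed, label) pair. The result is always a
#' positive integer below 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param ... character labels identifying the stage (and, e.g., rat, session).
#' @return a single integer seed.
#' @export
#' @examples
#' child_seed(1, "traces", "GT", 3)
child_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(if (h < 1) 1 else h)
}

# Draw from a normal truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) {
    return(rep(min(max(mean, lo), hi), n))
  }
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
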