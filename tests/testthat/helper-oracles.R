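# Independent brute-force oracles, written directly from the stated
# definitions and kept free of the package's implementation paths.

# Naive O(n^2) peak finder applying the three written criteria per sample:
# (1) value > mean + 3 sd; (2) the signal drops to <= value - sd on both
# sides before exceeding the value (pre-window treated as baseline-level,
# window end satisfies the drop; ties block on the left only, keeping the
# earliest of equal maxima); (3) supra-threshold runs without a criterion-2
# peak and with range < sd contribute their earliest maximum.
oracle_detect_peaks <- function(v, m, s) {
  n <- length(v)
  theta <- m + 3 * s
  accepted <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] <= theta) next
    left_ok <- TRUE
    j <- i - 1
    while (j >= 1) {
      if (v[j] <= v[i] - s) break       # drop found
      if (v[j] >= v[i]) { left_ok <- FALSE; break }
      j <- j - 1
    }
    # j == 0: reached the window start; baseline level satisfies the drop
    right_ok <- TRUE
    j <- i + 1
    while (j <= n) {
      if (v[j] <= v[i] - s) break
      if (v[j] > v[i]) { right_ok <- FALSE; break }
      j <- j + 1
    }
    if (left_ok && right_ok) accepted <- c(accepted, i)
  }
  extra <- integer(0)
  run_start <- NA
  for (i in seq_len(n + 1)) {
    above <- i <= n && v[i] > theta
    if (above && is.na(run_start)) run_start <- i
    if (!above && !is.na(run_start)) {
      idx <- run_start:(i - 1)
      if (!any(accepted %in% idx) && diff(range(v[idx])) < s) {
        extra <- c(extra, idx[which.max(v[idx])])
      }
      run_start <- NA
    }
  }
  sort(c(accepted, extra))
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Koopman-type score statistic with the constrained MLE found numerically
# (profile likelihood maximization), then the interval located by scanning a
# fine log-spaced grid of ratio values.
oracle_koopman_stat <- function(x1, n1, x2, n2, rho) {
  loglik <- function(p2) {
    p1 <- rho * p2
    if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) return(-Inf)
    x1 * log(p1) + (n1 - x1) * log(1 - p1) +
      x2 * log(p2) + (n2 - x2) * log(1 - p2)
  }
  upper <- min(1, 1 / rho) - 1e-12
  opt <- stats::optimize(loglik, interval = c(1e-12, upper), maximum = TRUE,
                         tol = 1e-12)
  p2 <- opt$maximum
  p1 <- rho * p2
  v <- p1 * (1 - p1) / n1 + rho^2 * p2 * (1 - p2) / n2
  (x1 / n1 - rho * x2 / n2)^2 / v
}

oracle_koopman_ci <- function(x1, n1, x2, n2, level = 0.95) {
  crit <- stats::qchisq(level, 1)
  rr <- (x1 / n1) / (x2 / n2)
  grid <- exp(seq(log(rr) - 4, log(rr) + 4, length.out = 80001))
  inside <- vapply(grid, function(r) {
    oracle_koopman_stat(x1, n1, x2, n2, r) <= crit
  }, logical(1))
  c(grid[which(inside)[1]], grid[rev(which(inside))[1]])
}

# Random short windows mixing flat noise, isolated spikes and plateaus,
# exercising all three criteria.
random_window <- function(n = 10, sd = 1) {
  base <- stats::rnorm(n, 0, sd)
  k <- sample(0:3, 1)
  if (k > 0) {
    at <- sample(n, k)
    base[at] <- base[at] + stats::runif(k, 2 * sd, 8 * sd)
  }
  if (stats::runif(1) < 0.3) { # sustained elevation
    i <- sample(n - 2, 1)
    base[i:(i + 2)] <- stats::runif(1, 3 * sd, 5 * sd) +
      stats::rnorm(3, 0, 0.3 * sd)
  }
  base
}
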