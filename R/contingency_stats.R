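#' Build a 2x2 phenotype-by-outcome contingency table
#'
#' @param gt_turns,gt_misses,st_turns,st_misses non-negative counts.
#' @return a list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(gt_turns, gt_misses, st_turns, st_misses) {
  counts <- c(gt_turns = gt_turns, gt_misses = gt_misses,
              st_turns = st_turns, st_misses = st_misses)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "contingency_2x2")
}

as_matrix_2x2 <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    matrix(c(table$gt_turns, table$gt_misses, table$st_turns, table$st_misses),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("GT", "ST"), c("turn", "miss")))
  } else if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    table
  } else {
    stop("expected a contingency_2x2 or a 2x2 matrix", call. = FALSE)
  }
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p value is the sum of the hypergeometric probabilities,
#' over all tables with the observed margins, of tables at most as probable
#' as the observed one (the probability-mass convention, with a relative
#' tolerance of about 1e-7 on the comparison).
#'
#' @param table a [contingency_2x2()] or a 2x2 count matrix.
#' @return the two-sided p value in (0, 1].
#' @export
#' @examples
#' fisher_exact(contingency_2x2(2, 0, 0, 2)) # 1/3
fisher_exact <- function(table) {
  m <- as_matrix_2x2(table)
  if (sum(m) == 0) stop("table has no observations", call. = FALSE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

# Koopman asymptotic-score chi-square statistic for H0: p1 = rho * p2,
# with constrained maximum-likelihood estimates of the two proportions.
koopman_statistic <- function(x1, n1, x2, n2, rho) {
  # constrained MLE of p2 under p1 = rho p2 (root of the score quadratic)
  a <- rho * (n1 + n2)
  b <- -(rho * n1 + x1 + n2 + rho * x2)
  cc <- x1 + x2
  disc <- max(0, b^2 - 4 * a * cc)
  p2 <- (-b - sqrt(disc)) / (2 * a)
  eps <- 1e-12
  p2 <- min(max(p2, eps), 1 - eps)
  p1 <- min(max(rho * p2, eps), 1 - eps)
  v <- p1 * (1 - p1) / n1 + rho^2 * p2 * (1 - p2) / n2
  stat <- (x1 / n1 - rho * x2 / n2)^2 / v
  if (!is.finite(stat) || v <= 0) Inf else stat
}

#' Relative probability with Koopman asymptotic-score interval
#'
#' Computes the relative probability (risk ratio) of a turn in GTs versus
#' STs and its confidence interval by inverting the asymptotic score test
#' for the ratio of two binomial proportions: the interval is the set of
#' ratio values whose score chi-square statistic (with constrained
#' maximum-likelihood proportions) does not exceed the corresponding
#' chi-square quantile. Endpoints are located by root-finding on each side
#' of the point estimate, with a grid-search fallback on numerical failure.
#' Transposing the phenotypes yields the reciprocal ratio with the interval
#' inverted.
#'
#' @param table a [contingency_2x2()] or 2x2 count matrix (rows GT/ST,
#'   columns turn/miss).
#' @param level confidence level (default 0.95).
#' @return a list of class `relative_probability_result`: `rr`, `ci_low`,
#'   `ci_high`, `p_fisher`, `level`, and `one_sided` (`TRUE` when a zero
#'   cell makes the estimate or an endpoint degenerate).
#' @export
#' @examples
#' koopman_rr_ci(contingency_2x2(206, 112, 158, 72))$rr # ~0.943
koopman_rr_ci <- function(table, level = 0.95) {
  m <- as_matrix_2x2(table)
  x1 <- m[1, 1]; n1 <- sum(m[1, ])
  x2 <- m[2, 1]; n2 <- sum(m[2, ])
  if (n1 == 0 || n2 == 0) stop("both phenotype totals must be > 0", call. = FALSE)

  crit <- qchisq(level, df = 1)
  f <- function(rho) koopman_statistic(x1, n1, x2, n2, rho) - crit

  rr <- if (x2 == 0) {
    if (x1 == 0) NaN else Inf
  } else {
    (x1 / n1) / (x2 / n2)
  }
  one_sided <- x1 == 0 || x2 == 0 || x1 == n1 || x2 == n2

  # search anchor inside the interval: the point estimate, or a finite proxy
  anchor <- if (is.finite(rr) && rr > 0) {
    rr
  } else if (x2 == 0 && x1 > 0) {
    (x1 / n1) / ((x2 + 0.5) / n2)
  } else {
    ((x1 + 0.5) / n1) / ((x2 + 0.5) / n2)
  }

  lo <- if (x1 == 0) {
    0
  } else {
    invert_side(f, anchor, lower = TRUE)
  }
  hi <- if (x2 == 0) {
    Inf
  } else {
    invert_side(f, anchor, lower = FALSE)
  }

  structure(list(rr = rr, ci_low = lo, ci_high = hi,
                 p_fisher = fisher_exact(m), level = level,
                 one_sided = one_sided),
            class = "relative_probability_result")
}

# Find the interval endpoint on one side of the anchor by bisection
# (uniroot), expanding the bracket geometrically; falls back to a fine grid
# on log(rho) when no sign change is found.
invert_side <- function(f, anchor, lower) {
  step <- if (lower) 0.5 else 2
  bound <- anchor
  for (k in 1:60) {
    bound <- bound * step
    if (f(bound) > 0) {
      iv <- sort(c(bound, anchor))
      root <- tryCatch(
        uniroot(f, interval = iv, tol = 1e-9)$root,
        error = function(e) NULL)
      if (!is.null(root)) return(root)
      break
    }
  }
  # grid fallback
  grid <- exp(seq(log(anchor) + if (lower) -40 else 0,
                  log(anchor) + if (lower) 0 else 40, length.out = 20001))
  inside <- vapply(grid, function(r) f(r) <= 0, logical(1))
  if (!any(inside)) return(if (lower) 0 else Inf)
  if (lower) grid[which(inside)[1]] else grid[rev(which(inside))[1]]
}

#' @export
print.relative_probability_result <- function(x, ...) {
  cat(sprintf("relative turn probability %.3f (%.0f%% score CI %.3f-%.3f), Fisher p = %.4g\n",
              x$rr, 100 * x$level, x$ci_low, x$ci_high, x$p_fisher))
  invisible(x)
}

#' Threshold sweep of turn/miss contingencies over peak features
#'
#' For each maximum-peak threshold and peak-count class (`any`: at least one
#' peak; `single`: exactly one; `multi`: two or three), restricts the traces
#' to those meeting both conditions (`max_peak >= threshold`, the figure's
#' at-or-above convention, configurable to strict `>`), builds the 2x2
#' turn/miss table by phenotype, and computes the relative turn probability,
#' its Koopman score interval, and the Fisher exact p. Conditions with any
#' cell count below `min_cell` (default 10) are flagged `included = FALSE`.
#'
#' @param features data frame with `phenotype` ("GT"/"ST"), `outcome`
#'   ("turn"/"miss"), `max_peak` (uM, `NA` when no peak) and `n_peaks`.
#' @param thresholds numeric vector of thresholds in uM.
#' @param peak_classes subset of `c("any", "single", "multi")`.
#' @param min_cell minimum cell count for inclusion.
#' @param strict use strict `>` instead of `>=` for the threshold.
#' @return a data frame of class `sweep_result`, one row per (class,
#'   threshold): cells, `n`, `rr`, `ci_low`, `ci_high`, `p_fisher`,
#'   `included`.
#' @export
threshold_sweep <- function(features,
                            thresholds = c(2, 2.8, 4, 6, 8),
                            peak_classes = c("any", "single", "multi"),
                            min_cell = 10,
                            strict = FALSE) {
  needed <- c("phenotype", "outcome", "max_peak", "n_peaks")
  if (!is.data.frame(features) || nrow(features) == 0) {
    stop("features must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(needed %in% names(features)))
  peak_classes <- match.arg(peak_classes, several.ok = TRUE)

  class_pred <- list(
    any = function(np) np >= 1,
    single = function(np) np == 1,
    multi = function(np) np %in% c(2, 3)
  )
  rows <- list()
  for (cls in peak_classes) {
    for (thr in thresholds) {
      sel <- !is.na(features$max_peak) &
        (if (strict) features$max_peak > thr else features$max_peak >= thr) &
        class_pred[[cls]](features$n_peaks)
      sub <- features[sel, , drop = FALSE]
      cells <- c(
        gt_turns = sum(sub$phenotype == "GT" & sub$outcome == "turn"),
        gt_misses = sum(sub$phenotype == "GT" & sub$outcome == "miss"),
        st_turns = sum(sub$phenotype == "ST" & sub$outcome == "turn"),
        st_misses = sum(sub$phenotype == "ST" & sub$outcome == "miss")
      )
      included <- all(cells >= min_cell)
      gt_total <- cells[1] + cells[2]
      st_total <- cells[3] + cells[4]
      if (gt_total > 0 && st_total > 0) {
        res <- koopman_rr_ci(do.call(contingency_2x2, as.list(cells)))
        rr <- res$rr; lo <- res$ci_low; hi <- res$ci_high; p <- res$p_fisher
      } else {
        rr <- NA_real_; lo <- NA_real_; hi <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        peak_class = cls, threshold = thr,
        gt_turns = cells[1], gt_misses = cells[2],
        st_turns = cells[3], st_misses = cells[4],
        n = sum(cells), rr = rr, ci_low = lo, ci_high = hi,
        p_fisher = p, included = included,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Pearson chi-square test for an r x c frequency table
#'
#' @param freq_table count matrix (r x c) with positive margins and all
#'   expected counts > 0.
#' @return list with `statistic`, `df`, `p`.
#' @export
#' @examples
#' pearson_chi_square(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))$statistic # 20
pearson_chi_square <- function(freq_table) {
  m <- as.matrix(freq_table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) stop("expected counts must be > 0", call. = FALSE)
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
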