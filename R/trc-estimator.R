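# Per-panel test-retest coefficient and its Monte Carlo distribution.

# Deterministic child-seed stream: (root + index * 48271) mod (2^31 - 1).
# Keeps every derived seed a valid 32-bit integer and makes replicate
# results independent of evaluation order.
child_seed <- function(root, index) {
  m <- 2147483647
  as.integer((as.numeric(root) %% m + (as.numeric(index) %% m) * 48271) %% m)
}

#' Pearson product-moment correlation with a defined degenerate case
#'
#' The test-retest coefficient of one panel. If either input has zero
#' sample variance the correlation is undefined and `NA` is returned
#' (silently) rather than an error, so that degenerate replicates can be
#' counted and dropped by the pipeline.
#'
#' @param x1,x2 Numeric vectors of equal length at least 2.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)) # 0.6
#' @export
pearson_r <- function(x1, x2) {
  if (!is.numeric(x1) || !is.numeric(x2) || length(x1) != length(x2) ||
      length(x1) < 2L) {
    stop_invalid("`x1` and `x2` must be numeric vectors of equal length >= 2")
  }
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    return(NA_real_)
  }
  stats::cor(x1, x2)
}

#' Monte Carlo distribution of the test-retest coefficient
#'
#' Simulates `reps` independent panels of size `n` under one condition and
#' summarises the replicate-level Pearson correlations by their mean (the
#' coefficient's accuracy) and standard deviation (its stability). Each
#' replicate uses a child seed derived deterministically from `seed` and the
#' replicate index, so results are reproducible and independent of
#' evaluation order. Replicates with undefined correlation (possible only
#' for degenerate variance settings) are dropped and counted.
#'
#' @param spec A [condition_spec()].
#' @param n Per-replicate sample size, at least 2.
#' @param reps Number of replicates, at least 2.
#' @param seed Root RNG seed.
#' @param fixed_tau If `TRUE`, panels come from [generate_fixed_tau()]
#'   (the copied-true-score representation of perfect stability) instead of
#'   [generate_scores()].
#' @return An object of class `trc_distribution` with fields `values`,
#'   `mean_trc`, `sd_trc`, `n`, `reps_requested`, `reps_used`, `dropped`.
#' @examples
#' d <- replicate_condition(condition_spec(9, 1, tau_stability = 0.8),
#'                          n = 200, reps = 50, seed = 1)
#' d$mean_trc
#' @export
replicate_condition <- function(spec, n, reps, seed, fixed_tau = FALSE) {
  spec <- as_condition_spec(spec)
  n <- check_sample_size(n)
  reps <- check_scalar(reps, "reps")
  if (reps < 2 || reps != floor(reps)) {
    stop_invalid("`reps` must be an integer of at least 2")
  }
  reps <- as.integer(reps)
  gen <- if (fixed_tau) generate_fixed_tau else generate_scores
  values <- vapply(seq_len(reps), function(k) {
    p <- gen(spec, n, child_seed(seed, k))
    pearson_r(p$x1, p$x2)
  }, numeric(1))
  used <- values[!is.na(values)]
  dropped <- reps - length(used)
  if (length(used) == 0L) {
    stop_invalid("all replicates had undefined correlations")
  }
  if (dropped > 0L) {
    warning(sprintf("%d of %d replicates had undefined correlations and were dropped",
                    dropped, reps), call. = FALSE)
  }
  structure(
    list(
      values = used,
      mean_trc = mean(used),
      sd_trc = stats::sd(used),
      n = n,
      reps_requested = reps,
      reps_used = length(used),
      dropped = dropped,
      spec = spec,
      seed = seed,
      fixed_tau = fixed_tau
    ),
    class = "trc_distribution"
  )
}

#' @export
print.trc_distribution <- function(x, ...) {
  cat(sprintf("TRC distribution: n = %d, %d/%d replicates used\n",
              x$n, x$reps_used, x$reps_requested))
  cat(sprintf("  mean TRC = %.4f, SD = %.4f (expected %.4f)\n",
              x$mean_trc, x$sd_trc, expected_trc_dependent(x$spec)))
  if (x$n == 2L) {
    cat("  note: n = 2 gives r = +/-1 almost surely; summaries are degenerate\n")
  }
  invisible(x)
}

#' Large-sample standard deviation of Pearson's r
#'
#' The classical approximation \eqn{(1 - \rho^2) / \sqrt{n - 1}} to the
#' sampling standard deviation of the correlation coefficient; used as an
#' analytic reference for the Monte Carlo coefficient-stability estimates.
#'
#' @param rho Population correlation(s), `|rho| <= 1`. Vectorised.
#' @param n Sample size(s), at least 2. Vectorised.
#' @return Approximate standard deviation(s) of the sample correlation.
#' @examples
#' sd_asymptotic(0.9, 17)
#' @export
sd_asymptotic <- function(rho, n) {
  if (!is.numeric(rho) || !is.numeric(n) || any(abs(rho) > 1) || any(n < 2)) {
    stop_invalid("require |rho| <= 1 and n >= 2")
  }
  (1 - rho^2) / sqrt(n - 1)
}
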