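# Coefficient-stability classification, minimum-sample-size search, and
# bias tabulation.

#' Coefficient-stability criteria
#'
#' A criterion is a named threshold on the standard deviation of replicate
#' TRC values: "good" stability means SD <= .05 (roughly 68% of estimates
#' within one conventional reliability band), "excellent" means SD <= .025
#' (roughly 95%).
#'
#' @param label `"good"` or `"excellent"`.
#' @return An object of class `stability_criterion` with fields `label` and
#'   `sd_threshold`.
#' @export
stability_criterion <- function(label = c("good", "excellent")) {
  label <- match.arg(label)
  structure(
    list(label = label,
         sd_threshold = if (label == "good") 0.05 else 0.025),
    class = "stability_criterion"
  )
}

#' Classify the stability of a TRC distribution
#'
#' @param sd_trc Standard deviation(s) of replicate TRC values, `>= 0`.
#' @return Character vector: `"excellent"` (SD <= .025), `"good"`
#'   (SD <= .05), else `"unstable"`.
#' @examples
#' classify_stability(c(0.02, 0.049, 0.3))
#' @export
classify_stability <- function(sd_trc) {
  if (!is.numeric(sd_trc) || any(!is.finite(sd_trc)) || any(sd_trc < 0)) {
    stop_invalid("`sd_trc` must be non-negative")
  }
  ifelse(sd_trc <= 0.025, "excellent",
         ifelse(sd_trc <= 0.05, "good", "unstable"))
}

#' Default sample-size search grid
#'
#' Candidate sample sizes from 2 up to the 1000-participant ceiling used by
#' the simulation studies; dense at small n where the sampling SD of r
#' changes fastest, coarser above 100.
#'
#' @return An increasing integer vector.
#' @export
default_n_grid <- function() {
  c(2L, 3L, 5L, 8L, 10L, 15L, 20L, 25L, 30L, 40L, 50L, 75L, 100L, 150L,
    200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L)
}

#' Minimum sample size for stable TRC estimation
#'
#' Evaluates the Monte Carlo SD of the TRC at each candidate sample size
#' and returns the smallest grid point from which the stability criterion
#' holds there *and at every larger grid point* (the sustained-crossing
#' rule, which is robust to SD-estimate noise near the threshold). If the
#' criterion is never sustained within the grid, `min_n` is `NA` and
#' `reached` is `FALSE` (the search hit the ceiling).
#'
#' @param spec A [condition_spec()].
#' @param criterion `"good"`, `"excellent"`, or a [stability_criterion()].
#' @param grid Strictly increasing candidate sample sizes, all `<= ceiling`.
#' @param reps Replicates per grid point.
#' @param seed Root seed; each grid point gets its own child stream.
#' @param fixed_tau Passed to [replicate_condition()].
#' @param ceiling Largest admissible sample size (default 1000).
#' @return An object of class `min_n_result` with the grid, the SD profile,
#'   `min_n` (or `NA`), and `reached`.
#' @examples
#' r <- min_sample_size(condition_spec(9, 1), "good",
#'                      grid = c(10, 20, 50), reps = 100, seed = 1,
#'                      fixed_tau = TRUE)
#' r$min_n
#' @export
min_sample_size <- function(spec, criterion = "good", grid = default_n_grid(),
                            reps = 1000, seed = 1, fixed_tau = FALSE,
                            ceiling = 1000) {
  spec <- as_condition_spec(spec)
  if (is.character(criterion)) {
    criterion <- stability_criterion(criterion)
  }
  if (!inherits(criterion, "stability_criterion")) {
    stop_invalid("`criterion` must be \"good\", \"excellent\", or a stability_criterion")
  }
  if (length(grid) == 0L) {
    stop_invalid("`grid` must be non-empty")
  }
  if (any(diff(grid) <= 0)) {
    stop_invalid("`grid` must be strictly increasing")
  }
  if (max(grid) > ceiling) {
    stop_invalid("`grid` exceeds the configured ceiling of ", ceiling)
  }
  sd_profile <- vapply(seq_along(grid), function(i) {
    replicate_condition(spec, grid[i], reps,
                        seed = child_seed(seed, i * 1000003),
                        fixed_tau = fixed_tau)$sd_trc
  }, numeric(1))
  met <- sd_profile <= criterion$sd_threshold
  sustained <- rev(cumprod(rev(met))) > 0
  idx <- which(sustained)
  structure(
    list(
      spec = spec,
      criterion = criterion,
      min_n = if (length(idx)) as.integer(grid[idx[1]]) else NA_integer_,
      reached = length(idx) > 0L,
      grid = as.integer(grid),
      sd_profile = sd_profile,
      reps = reps,
      seed = seed,
      ceiling = ceiling,
      fixed_tau = fixed_tau
    ),
    class = "min_n_result"
  )
}

#' @export
print.min_n_result <- function(x, ...) {
  shown <- if (x$reached) format(x$min_n) else paste0(">", x$ceiling)
  cat(sprintf("Minimum n for %s stability (SD <= %.3f): %s\n",
              x$criterion$label, x$criterion$sd_threshold, shown))
  cat(sprintf("  grid %d..%d, %d replicates per point\n",
              min(x$grid), max(x$grid), x$reps))
  invisible(x)
}

#' Tabulate TRC bias across conditions
#'
#' For each condition: the reliability ratio, the closed-form expected TRC,
#' the simulated mean and SD across replicates, and both the closed-form
#' bias (reliability minus expected TRC) and the simulated bias
#' (reliability minus mean simulated TRC).
#'
#' @param specs A [condition_spec()] or a list of them.
#' @param n Per-replicate sample size.
#' @param reps Replicates per condition.
#' @param seed Root seed; conditions get independent child streams.
#' @param fixed_tau If `TRUE`, conditions with `tau_stability == 1` use the
#'   copied-true-score generator.
#' @return A tibble with one row per condition.
#' @examples
#' bias_table(condition_spec(9, 1, tau_stability = 0.8),
#'            n = 500, reps = 50, seed = 1)
#' @export
bias_table <- function(specs, n = 1000, reps = 1000, seed = 1,
                       fixed_tau = TRUE) {
  if (inherits(specs, "condition_spec")) {
    specs <- list(specs)
  }
  if (!is.list(specs) || length(specs) == 0L ||
      !all(vapply(specs, inherits, logical(1), "condition_spec"))) {
    stop_invalid("`specs` must be one or more condition_spec objects")
  }
  rows <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    rel <- reliability_from_variances(spec)
    exp_trc <- expected_trc_dependent(spec)
    d <- replicate_condition(
      spec, n, reps,
      seed = child_seed(seed, i * 1000003),
      fixed_tau = fixed_tau && spec$tau_stability == 1
    )
    tibble::tibble(
      true_var = spec$true_var,
      error_var = spec$error_var,
      tau_stability = spec$tau_stability,
      error_dependence = spec$error_dependence,
      reliability = rel,
      expected_trc = exp_trc,
      mean_trc = d$mean_trc,
      sd_trc = d$sd_trc,
      bias_closed = rel - exp_trc,
      bias_sim = rel - d$mean_trc,
      reps_used = d$reps_used,
      dropped = d$dropped
    )
  })
  do.call(rbind, rows)
}
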