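# Orchestration of the two simulation-study grids and the command line.

#' Configure a simulation study
#'
#' Study 1 crosses true-score stability with a grid of true/error variance
#' pairs under independent errors, the perfectly-stable level running
#' through the copied-true-score generator. Study 2 crosses stability with
#' error-score dependence over a reliability grid, holding total variance
#' fixed at `total_variance` (the absolute scale is immaterial: all outputs
#' depend on the variances only through their ratio).
#'
#' The `"full"` scale reproduces the complete grids (1000 replicates;
#' Study 1: stability 1 down to .5 by .1 over all 81 variance pairs from
#' \{1..9\}^2; Study 2: stability \{1, .9, .8, .7, .6\}, error dependence
#' \{.1, .3, .5\}, reliability .60 to .95 by .05). The `"desk"` scale keeps
#' the scientifically load-bearing corners at 200 replicates so a study
#' finishes in minutes on one CPU.
#'
#' @param study `"study1"` or `"study2"`.
#' @param scale `"desk"` or `"full"`.
#' @param n_grid Per-replicate sample sizes to evaluate.
#' @param reps Replicates per condition.
#' @param seed Root seed.
#' @param tau_stability_levels True-score stability levels.
#' @param error_dependence_levels Error-score correlation levels (Study 1
#'   forces `0`).
#' @param variance_grid Study 1 only: data frame with columns `true_var`,
#'   `error_var`.
#' @param reliability_levels Study 2 only: variance-ratio levels.
#' @param total_variance Study 2 only: common total variance.
#' @return An object of class `study_config`.
#' @examples
#' study_config("study1", scale = "desk", seed = 42)
#' @export
study_config <- function(study = c("study1", "study2"),
                         scale = c("desk", "full"),
                         n_grid = NULL, reps = NULL, seed = 1,
                         tau_stability_levels = NULL,
                         error_dependence_levels = NULL,
                         variance_grid = NULL,
                         reliability_levels = NULL,
                         total_variance = 10) {
  study <- match.arg(study)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  if (is.null(reps)) reps <- if (desk) 200L else 1000L
  if (study == "study1") {
    if (is.null(tau_stability_levels)) {
      tau_stability_levels <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
    }
    if (!is.null(error_dependence_levels) &&
        any(error_dependence_levels != 0)) {
      stop_invalid("config error in `error_dependence_levels`: study1 uses independent errors (0 only)")
    }
    error_dependence_levels <- 0
    if (is.null(variance_grid)) {
      variance_grid <- if (desk) {
        data.frame(true_var = c(6, 7, 8, 9), error_var = c(4, 3, 2, 1))
      } else {
        expand.grid(true_var = 1:9, error_var = 1:9, KEEP.OUT.ATTRS = FALSE)
      }
    }
    if (!is.data.frame(variance_grid) ||
        !all(c("true_var", "error_var") %in% names(variance_grid))) {
      stop_invalid("config error in `variance_grid`: need columns true_var, error_var")
    }
    if (is.null(n_grid)) {
      n_grid <- if (desk) c(25L, 50L, 100L, 200L, 500L, 1000L) else default_n_grid()
    }
  } else {
    if (is.null(tau_stability_levels)) {
      tau_stability_levels <- c(1, 0.9, 0.8, 0.7, 0.6)
    }
    if (is.null(error_dependence_levels)) {
      error_dependence_levels <- c(0.1, 0.3, 0.5)
    }
    if (is.null(reliability_levels)) {
      reliability_levels <- if (desk) c(0.6, 0.7, 0.8, 0.9) else seq(0.60, 0.95, by = 0.05)
    }
    if (any(reliability_levels <= 0) || any(reliability_levels >= 1)) {
      stop_invalid("config error in `reliability_levels`: must lie in (0, 1)")
    }
    if (is.null(n_grid)) {
      n_grid <- if (desk) c(100L, 500L, 1000L) else default_n_grid()
    }
  }
  if (any(tau_stability_levels < 0) || any(tau_stability_levels > 1)) {
    stop_invalid("config error in `tau_stability_levels`: must lie in [0, 1]")
  }
  if (any(error_dependence_levels < 0) || any(error_dependence_levels >= 1)) {
    stop_invalid("config error in `error_dependence_levels`: must lie in [0, 1)")
  }
  if (any(n_grid < 2) || any(diff(as.numeric(n_grid)) <= 0)) {
    stop_invalid("config error in `n_grid`: must be strictly increasing sample sizes >= 2")
  }
  if (reps < 2) {
    stop_invalid("config error in `reps`: need at least 2 replicates")
  }
  structure(
    list(
      study = study, scale = scale,
      n_grid = as.integer(n_grid), reps = as.integer(reps),
      seed = seed,
      tau_stability_levels = tau_stability_levels,
      error_dependence_levels = error_dependence_levels,
      variance_grid = variance_grid,
      reliability_levels = reliability_levels,
      total_variance = total_variance
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("%s (%s scale): %d replicates, seed %s\n",
              x$study, x$scale, x$reps, format(x$seed)))
  cat(sprintf("  n grid: %s\n", paste(x$n_grid, collapse = ", ")))
  cat(sprintf("  tau stability: %s\n",
              paste(x$tau_stability_levels, collapse = ", ")))
  if (x$study == "study1") {
    cat(sprintf("  variance pairs: %d\n", nrow(x$variance_grid)))
  } else {
    cat(sprintf("  error dependence: %s\n",
                paste(x$error_dependence_levels, collapse = ", ")))
    cat(sprintf("  reliability levels: %s\n",
                paste(x$reliability_levels, collapse = ", ")))
  }
  invisible(x)
}

# Shared grid evaluator: `conditions` is a data.frame of condition
# coordinates with columns true_var, error_var, tau_stability,
# error_dependence; each (condition x n) cell gets a deterministic child
# stream keyed by its row index.
run_grid <- function(study, conditions, n_grid, reps, seed, fixed_tau_at_1) {
  cells <- merge(cbind(conditions, .cond = seq_len(nrow(conditions))),
                 data.frame(n = n_grid))
  cells <- cells[order(cells$.cond, cells$n), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    spec <- condition_spec(cell$true_var, cell$error_var,
                           tau_stability = cell$tau_stability,
                           error_dependence = cell$error_dependence)
    rel <- reliability_from_variances(spec)
    d <- replicate_condition(
      spec, cell$n, reps,
      seed = child_seed(seed, i * 1000003),
      fixed_tau = fixed_tau_at_1 && cell$tau_stability == 1
    )
    tibble::tibble(
      study = study,
      n = cell$n,
      true_var = cell$true_var,
      error_var = cell$error_var,
      reliability = rel,
      tau_stability = cell$tau_stability,
      error_dependence = cell$error_dependence,
      expected_trc = expected_trc_dependent(spec),
      mean_trc = d$mean_trc,
      sd_trc = d$sd_trc,
      bias = rel - d$mean_trc,
      reps_used = d$reps_used,
      dropped = d$dropped
    )
  })
  do.call(rbind, rows)
}

#' Run the Study 1 grid (stability x variance ratio, independent errors)
#'
#' @param config A [study_config()] with `study = "study1"`.
#' @return A tibble with one row per condition and sample size, carrying
#'   the closed-form expected TRC alongside the Monte Carlo mean, SD, and
#'   bias.
#' @examples
#' cfg <- study_config("study1", n_grid = c(50, 200), reps = 50, seed = 1,
#'                     variance_grid = data.frame(true_var = 9, error_var = 1))
#' run_study1(cfg)
#' @export
run_study1 <- function(config) {
  if (!inherits(config, "study_config") || config$study != "study1") {
    stop_invalid("config error in `study`: run_study1 needs a study1 config")
  }
  conditions <- merge(config$variance_grid,
                      data.frame(tau_stability = config$tau_stability_levels))
  conditions$error_dependence <- 0
  conditions <- conditions[order(conditions$tau_stability,
                                 conditions$true_var,
                                 conditions$error_var), , drop = FALSE]
  run_grid("study1", conditions, config$n_grid, config$reps, config$seed,
           fixed_tau_at_1 = TRUE)
}

#' Run the Study 2 grid (stability x error dependence x reliability)
#'
#' Reliability levels are realised as variance pairs with total variance
#' `config$total_variance`; the perfectly-stable level runs through the
#' correlated-normal generator with stability 1 (equivalent in distribution
#' to the copied-true-score path).
#'
#' @param config A [study_config()] with `study = "study2"`.
#' @return A tibble, one row per condition and sample size; the
#'   `expected_trc` column is the variance-weighted sum of stability and
#'   error dependence.
#' @export
run_study2 <- function(config) {
  if (!inherits(config, "study_config") || config$study != "study2") {
    stop_invalid("config error in `study`: run_study2 needs a study2 config")
  }
  conditions <- expand.grid(
    reliability = config$reliability_levels,
    tau_stability = config$tau_stability_levels,
    error_dependence = config$error_dependence_levels,
    KEEP.OUT.ATTRS = FALSE
  )
  conditions$true_var <- config$total_variance * conditions$reliability
  conditions$error_var <- config$total_variance * (1 - conditions$reliability)
  conditions$reliability <- NULL
  run_grid("study2", conditions, config$n_grid, config$reps, config$seed,
           fixed_tau_at_1 = FALSE)
}

#' Write a study result table to CSV
#'
#' Plain CSV with a header row and the fixed column order of the result
#' tibble; reading it back with `read.csv` round-trips the values.
#'
#' @param table A result tibble from [run_study1()], [run_study2()], or
#'   [bias_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
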