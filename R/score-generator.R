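# Joint-normal generator for paired true, error, and observed scores.
#
# Sampling contract: draw standard-normal deviates, correlate them through a
# factor of the 4x4 *correlation* matrix over (tau1, tau2, eps1, eps2), then
# scale by the standard deviations and shift by the means. Because the
# correlated deviates never see the variances, rescaling both variances by a
# common factor rescales the observed scores linearly, so any
# scale-invariant statistic (Pearson r in particular) is reproduced exactly
# under a shared seed.

#' Target covariance matrix of the score components
#'
#' Builds the 4x4 covariance of (tau1, tau2, eps1, eps2) implied by a
#' condition: equal variances within the true and error pairs, cross-occasion
#' covariances \eqn{r_\tau \sigma_\tau^2} and
#' \eqn{r_\epsilon \sigma_\epsilon^2}, and zero true-error covariance.
#'
#' @param spec A [condition_spec()].
#' @return A symmetric positive-semidefinite 4x4 matrix with dimnames
#'   `tau1, tau2, eps1, eps2`.
#' @examples
#' build_covariance(condition_spec(9, 1, tau_stability = 0.8))
#' @export
build_covariance <- function(spec) {
  spec <- as_condition_spec(spec)
  vt <- spec$true_var
  ve <- spec$error_var
  m <- matrix(0, 4, 4,
              dimnames = list(c("tau1", "tau2", "eps1", "eps2"),
                              c("tau1", "tau2", "eps1", "eps2")))
  m[1, 1] <- m[2, 2] <- vt
  m[3, 3] <- m[4, 4] <- ve
  m[1, 2] <- m[2, 1] <- spec$tau_stability * vt
  m[3, 4] <- m[4, 3] <- spec$error_dependence * ve
  m
}

# Factor F of a correlation matrix R such that t(F) %*% F = R.
# chol() for the regular case; symmetric eigendecomposition when R is
# singular (tau_stability = 1 makes the true-score block rank deficient).
correlation_factor <- function(r) {
  tryCatch(chol(r), error = function(e) {
    ev <- eigen(r, symmetric = TRUE)
    diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  })
}

new_score_panel <- function(tau1, tau2, eps1, eps2, spec, n, seed) {
  structure(
    list(
      tau1 = tau1, tau2 = tau2,
      eps1 = eps1, eps2 = eps2,
      x1 = tau1 + eps1, x2 = tau2 + eps2,
      n = n, spec = spec, seed = seed
    ),
    class = "score_panel"
  )
}

#' Generate paired true, error, and observed scores
#'
#' Draws `n` joint-normal quadruples (tau1, tau2, eps1, eps2) with means
#' (`true_mean`, `true_mean`, 0, 0) and the covariance from
#' [build_covariance()], and returns observed scores `x = tau + eps` for
#' both occasions. Reproducible: identical `(spec, n, seed)` give identical
#' panels, and multiplying both variances by a common factor rescales the
#' scores without changing the underlying deviates.
#'
#' @param spec A [condition_spec()].
#' @param n Sample size, at least 2.
#' @param seed Integer RNG seed.
#' @return An object of class `score_panel` with vectors `tau1`, `tau2`,
#'   `eps1`, `eps2`, `x1`, `x2`.
#' @examples
#' p <- generate_scores(condition_spec(9, 1, tau_stability = 0.8), 100, 1)
#' cor(p$x1, p$x2)
#' @export
generate_scores <- function(spec, n, seed) {
  spec <- as_condition_spec(spec)
  n <- check_sample_size(n)
  set.seed(as_seed(seed))
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- spec$tau_stability
  r[3, 4] <- r[4, 3] <- spec$error_dependence
  z <- matrix(stats::rnorm(4L * n), n, 4L) %*% correlation_factor(r)
  sd_t <- sqrt(spec$true_var)
  sd_e <- sqrt(spec$error_var)
  new_score_panel(
    tau1 = spec$true_mean + sd_t * z[, 1L],
    tau2 = spec$true_mean + sd_t * z[, 2L],
    eps1 = sd_e * z[, 3L],
    eps2 = sd_e * z[, 4L],
    spec = spec, n = n, seed = seed
  )
}

#' Generate scores with a fixed (copied) true score
#'
#' The perfectly-stable condition: a single true-score vector is drawn and
#' copied to the second occasion, so `tau1 == tau2` exactly; error scores
#' are drawn independently of it (with correlation `error_dependence`
#' between occasions if nonzero). Equivalent in distribution to
#' [generate_scores()] with `tau_stability = 1`.
#'
#' @inheritParams generate_scores
#' @return A `score_panel` with `tau2` an exact copy of `tau1`.
#' @export
generate_fixed_tau <- function(spec, n, seed) {
  spec <- as_condition_spec(spec)
  n <- check_sample_size(n)
  set.seed(as_seed(seed))
  zt <- stats::rnorm(n)
  r <- matrix(c(1, spec$error_dependence, spec$error_dependence, 1), 2L, 2L)
  ze <- matrix(stats::rnorm(2L * n), n, 2L) %*% chol(r)
  tau1 <- spec$true_mean + sqrt(spec$true_var) * zt
  sd_e <- sqrt(spec$error_var)
  new_score_panel(
    tau1 = tau1, tau2 = tau1,
    eps1 = sd_e * ze[, 1L],
    eps2 = sd_e * ze[, 2L],
    spec = spec, n = n, seed = seed
  )
}

check_sample_size <- function(n) {
  n <- check_scalar(n, "n")
  if (n < 2 || n != floor(n)) {
    stop_invalid("`n` must be an integer sample size of at least 2")
  }
  as.integer(n)
}

as_seed <- function(seed) {
  seed <- check_scalar(seed, "seed")
  as.integer(seed %% 2147483647)
}

#' @export
print.score_panel <- function(x, ...) {
  cat(sprintf("Score panel: n = %d (seed %s)\n", x$n, format(x$seed)))
  cat(sprintf("  observed r(x1, x2) = %s\n",
              format(pearson_r(x$x1, x$x2), digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.score_panel <- function(x, ...) {
  data.frame(
    id = seq_len(x$n),
    tau1 = x$tau1, tau2 = x$tau2,
    eps1 = x$eps1, eps2 = x$eps2,
    x1 = x$x1, x2 = x$x2
  )
}

#' Export a score panel to CSV
#'
#' Writes the panel as a plain CSV with columns
#' `id, tau1, tau2, eps1, eps2, x1, x2` for external inspection.
#'
#' @param panel A `score_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  if (!inherits(panel, "score_panel")) {
    stop_invalid("`panel` must be a score_panel")
  }
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
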