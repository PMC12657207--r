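# Closed-form classical-test-theory algebra for the test-retest coefficient.
# Everything in this file is pure and deterministic; no RNG.

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  as.numeric(x)
}

#' Specify one simulation condition
#'
#' A condition bundles the variance components and cross-occasion
#' correlations that determine the behaviour of the test-retest coefficient:
#' the true-score variance \eqn{\sigma_\tau^2}, the error-score variance
#' \eqn{\sigma_\epsilon^2}, the true-score stability \eqn{r_\tau} (the
#' correlation between the two occasions' true scores; 1 encodes a fixed
#' trait), and the error-score dependence \eqn{r_\epsilon} (systematic
#' error shared across administrations).
#'
#' Error scores have mean zero by definition of the measurement model; the
#' true-score mean is a free location parameter (default 10) that no output
#' of the package depends on.
#'
#' @param true_var True-score variance, \eqn{\ge 0} (score units squared).
#' @param error_var Error-score variance, \eqn{\ge 0}; `true_var + error_var`
#'   must be positive.
#' @param tau_stability Correlation between occasion-1 and occasion-2 true
#'   scores, in `[0, 1]`.
#' @param error_dependence Correlation between the two occasions' error
#'   scores, in `[0, 1)`.
#' @param true_mean Mean of the true-score distributions (score units).
#' @return An object of class `condition_spec`.
#' @examples
#' condition_spec(true_var = 9, error_var = 1, tau_stability = 0.8)
#' @export
condition_spec <- function(true_var, error_var, tau_stability = 1,
                           error_dependence = 0, true_mean = 10) {
  true_var <- check_scalar(true_var, "true_var")
  error_var <- check_scalar(error_var, "error_var")
  tau_stability <- check_scalar(tau_stability, "tau_stability")
  error_dependence <- check_scalar(error_dependence, "error_dependence")
  true_mean <- check_scalar(true_mean, "true_mean")
  if (true_var < 0 || error_var < 0) {
    stop_invalid("variances must be non-negative")
  }
  if (true_var + error_var <= 0) {
    stop_invalid("total variance must be positive")
  }
  if (tau_stability < 0 || tau_stability > 1) {
    stop_invalid("`tau_stability` must lie in [0, 1]")
  }
  if (error_dependence < 0 || error_dependence >= 1) {
    stop_invalid("`error_dependence` must lie in [0, 1)")
  }
  structure(
    list(
      true_var = true_var,
      error_var = error_var,
      tau_stability = tau_stability,
      error_dependence = error_dependence,
      true_mean = true_mean,
      error_mean = 0
    ),
    class = "condition_spec"
  )
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("Simulation condition\n")
  cat(sprintf("  variances      : tau^2 = %g, eps^2 = %g (reliability %.3f)\n",
              x$true_var, x$error_var, reliability_from_variances(x)))
  cat(sprintf("  tau stability  : %g\n", x$tau_stability))
  cat(sprintf("  error depend.  : %g\n", x$error_dependence))
  cat(sprintf("  means          : tau = %g, eps = 0\n", x$true_mean))
  invisible(x)
}

#' Reliability as a variance ratio
#'
#' Reliability in the classical model is the proportion of observed-score
#' variance attributable to true scores,
#' \eqn{\sigma_\tau^2 / (\sigma_\tau^2 + \sigma_\epsilon^2)}.
#'
#' @param true_var True-score variance, or a [condition_spec()] (in which
#'   case `error_var` is taken from it).
#' @param error_var Error-score variance.
#' @return The variance ratio in `(0, 1]`.
#' @examples
#' reliability_from_variances(9, 1) # 0.9
#' reliability_from_variances(6, 4) # 0.6
#' @export
reliability_from_variances <- function(true_var, error_var) {
  if (inherits(true_var, "condition_spec")) {
    spec <- true_var
    true_var <- spec$true_var
    error_var <- spec$error_var
  }
  true_var <- check_scalar(true_var, "true_var")
  error_var <- check_scalar(error_var, "error_var")
  if (true_var < 0 || error_var < 0) {
    stop_invalid("variances must be non-negative")
  }
  if (true_var + error_var <= 0) {
    stop_invalid("total variance must be positive")
  }
  true_var / (true_var + error_var)
}

#' Expected test-retest correlation under independent errors
#'
#' With independent error scores the expected TRC is the product of
#' true-score stability and reliability: imperfect stability attenuates the
#' observed correlation below the instrument's reliability.
#'
#' @param tau_stability True-score cross-occasion correlation in `[0, 1]`.
#'   Vectorised.
#' @param reliability Variance ratio in `[0, 1]`. Vectorised.
#' @return `tau_stability * reliability`, elementwise.
#' @examples
#' expected_trc(0.7, 0.9) # 0.63
#' @export
expected_trc <- function(tau_stability, reliability) {
  if (!is.numeric(tau_stability) || !is.numeric(reliability)) {
    stop_invalid("arguments must be numeric")
  }
  if (any(!is.finite(tau_stability)) || any(!is.finite(reliability)) ||
      any(tau_stability < 0) || any(tau_stability > 1) ||
      any(reliability < 0) || any(reliability > 1)) {
    stop_invalid("`tau_stability` and `reliability` must lie in [0, 1]")
  }
  tau_stability * reliability
}

#' Expected test-retest correlation under dependent errors
#'
#' When error scores are correlated across occasions the expected TRC is a
#' variance-weighted sum of true-score stability and error dependence:
#' \eqn{r_\tau \sigma_\tau^2/(\sigma_\tau^2+\sigma_\epsilon^2) +
#' r_\epsilon \sigma_\epsilon^2/(\sigma_\tau^2+\sigma_\epsilon^2)}.
#' Being a convex combination, the result always lies between
#' \eqn{\min(r_\tau, r_\epsilon)} and \eqn{\max(r_\tau, r_\epsilon)}; with
#' \eqn{r_\epsilon = 0} it reduces to [expected_trc()].
#'
#' @param spec A [condition_spec()].
#' @return The expected correlation between the two observed scores.
#' @examples
#' s <- condition_spec(9, 1, tau_stability = 0.6, error_dependence = 0.5)
#' expected_trc_dependent(s) # 0.59
#' @export
expected_trc_dependent <- function(spec) {
  spec <- as_condition_spec(spec)
  w <- reliability_from_variances(spec)
  spec$tau_stability * w + spec$error_dependence * (1 - w)
}

#' Bias of the test-retest coefficient relative to reliability
#'
#' The signed deviation of reliability from the expected TRC:
#' `reliability - expected TRC`. Positive values mean the coefficient
#' underestimates reliability (attenuation from unstable true scores);
#' negative values mean inflation above reliability (systematic error).
#'
#' @param spec A [condition_spec()].
#' @return Signed bias (dimensionless).
#' @examples
#' trc_bias(condition_spec(9, 1, tau_stability = 0.7)) # 0.27
#' @export
trc_bias <- function(spec) {
  spec <- as_condition_spec(spec)
  reliability_from_variances(spec) - expected_trc_dependent(spec)
}

as_condition_spec <- function(spec) {
  if (!inherits(spec, "condition_spec")) {
    stop_invalid("`spec` must be a condition_spec")
  }
  spec
}

#' Conventional reliability categories
#'
#' Interpretation thresholds for a test-retest coefficient: values of at
#' least .70 are "acceptable", at least .80 "good", at least .90
#' "excellent"; anything below .70 is "unacceptable". The lower bounds are
#' treated as inclusive so that classification is total.
#'
#' @return A data frame with columns `label` and `lower_bound`.
#' @export
reliability_categories <- function() {
  data.frame(
    label = c("unacceptable", "acceptable", "good", "excellent"),
    lower_bound = c(-1, 0.70, 0.80, 0.90),
    stringsAsFactors = FALSE
  )
}

#' Classify a test-retest coefficient into a reliability category
#'
#' @param trc_value Coefficient value(s) in `[-1, 1]`.
#' @return An ordered factor with levels `unacceptable < acceptable < good <
#'   excellent`.
#' @examples
#' classify_reliability(c(0.95, 0.70, -0.2))
#' @export
classify_reliability <- function(trc_value) {
  if (!is.numeric(trc_value) || any(!is.finite(trc_value)) ||
      any(trc_value < -1) || any(trc_value > 1)) {
    stop_invalid("`trc_value` must lie in [-1, 1]")
  }
  cats <- reliability_categories()
  idx <- vapply(trc_value, function(v) max(which(v >= cats$lower_bound)),
                integer(1))
  factor(cats$label[idx], levels = cats$label, ordered = TRUE)
}

#' Enumerate parameter combinations sharing the same expected TRC
#'
#' From two-occasion data alone, stability, reliability, and error
#' dependence are not separately identifiable: many (\eqn{r_\tau},
#' reliability, \eqn{r_\epsilon}) triples produce the same expected
#' coefficient. This enumerates a uniform grid over \eqn{[0,1]^3}
#' (with \eqn{r_\epsilon < 1}) and returns every triple whose expected TRC
#' falls within `tolerance` of the target.
#'
#' @param target_trc Target coefficient in `[0, 1]`.
#' @param grid_resolution Grid step for each of the three parameters.
#' @param tolerance Half-width of the acceptance band around `target_trc`.
#' @return An object of class `equivalence_set`: the target, tolerance,
#'   resolution, and a tibble of members with their expected TRC and the
#'   reliability category of each member's reliability value.
#' @examples
#' eq <- equivalent_conditions(0.63, grid_resolution = 0.1, tolerance = 0.005)
#' head(eq$members)
#' @export
equivalent_conditions <- function(target_trc, grid_resolution = 0.05,
                                  tolerance = 0.005) {
  target_trc <- check_scalar(target_trc, "target_trc")
  grid_resolution <- check_scalar(grid_resolution, "grid_resolution")
  tolerance <- check_scalar(tolerance, "tolerance")
  if (target_trc < 0 || target_trc > 1) {
    stop_invalid("`target_trc` must lie in [0, 1]")
  }
  if (grid_resolution <= 0 || grid_resolution > 1) {
    stop_invalid("`grid_resolution` must lie in (0, 1]")
  }
  if (tolerance < 0) {
    stop_invalid("`tolerance` must be non-negative")
  }
  axis <- seq(0, 1, by = grid_resolution)
  eps_axis <- axis[axis < 1]
  if (length(axis) == 0L || length(eps_axis) == 0L) {
    stop_invalid("enumeration grid is empty")
  }
  grid <- expand.grid(
    tau_stability = axis,
    reliability = axis,
    error_dependence = eps_axis,
    KEEP.OUT.ATTRS = FALSE
  )
  trc <- grid$tau_stability * grid$reliability +
    grid$error_dependence * (1 - grid$reliability)
  keep <- abs(trc - target_trc) <= tolerance
  members <- tibble::tibble(
    tau_stability = grid$tau_stability[keep],
    reliability = grid$reliability[keep],
    error_dependence = grid$error_dependence[keep],
    expected_trc = trc[keep],
    category = classify_reliability(grid$reliability[keep])
  )
  structure(
    list(
      target_trc = target_trc,
      tolerance = tolerance,
      grid_resolution = grid_resolution,
      members = members
    ),
    class = "equivalence_set"
  )
}

#' @export
print.equivalence_set <- function(x, ...) {
  cat(sprintf(
    "Equivalence set for TRC = %.3f (tolerance %.3g, grid step %.3g)\n",
    x$target_trc, x$tolerance, x$grid_resolution
  ))
  cat(sprintf("  %d member triple(s) spanning %d reliability categor%s\n",
              nrow(x$members),
              length(unique(x$members$category)),
              if (length(unique(x$members$category)) == 1L) "y" else "ies"))
  invisible(x)
}
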