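# Shared fixtures: conditions used throughout the suite, built in code.

spec_91 <- function(tau = 1, eps = 0) {
  condition_spec(9, 1, tau_stability = tau, error_dependence = eps)
}

spec_64 <- function(tau = 1, eps = 0) {
  condition_spec(6, 4, tau_stability = tau, error_dependence = eps)
}

# Monte Carlo standard error of a mean of `reps` replicate correlations.
mc_se <- function(sd_values, reps) sd_values / sqrt(reps)

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / stats::sd(x)^3
}
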