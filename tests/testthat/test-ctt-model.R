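test_that("reliability is the true-to-total variance ratio", {
  expect_equal(reliability_from_variances(9, 1), 0.9)
  expect_equal(reliability_from_variances(1, 1), 0.5)
  expect_equal(reliability_from_variances(6, 4), 0.6)
  expect_equal(reliability_from_variances(spec_91()), 0.9)
  expect_error(reliability_from_variances(0, 0), "total variance")
  expect_error(reliability_from_variances(-1, 2), "non-negative")
})

test_that("expected TRC is the stability-reliability product with identity limits", {
  expect_equal(expected_trc(0.7, 0.9), 0.63)
  expect_equal(expected_trc(0.8, 0.6), 0.48)
  p <- seq(0, 1, by = 0.05)
  expect_equal(expected_trc(rep(1, length(p)), p), p)
  expect_equal(expected_trc(p, rep(1, length(p))), p)
  expect_error(expected_trc(1.2, 0.5), "\\[0, 1\\]")
  expect_error(expected_trc(0.5, -0.1), "\\[0, 1\\]")
})

test_that("dependent-error TRC is a variance-weighted convex combination", {
  expect_equal(
    expected_trc_dependent(condition_spec(9, 1, tau_stability = 0.6,
                                          error_dependence = 0.5)),
    0.59
  )
  # equal component correlations collapse to that common value
  for (rho in c(0, 0.3, 0.85)) {
    expect_equal(
      expected_trc_dependent(condition_spec(3, 7, tau_stability = rho,
                                            error_dependence = rho)),
      rho
    )
  }
  # with independent errors it reduces exactly to the product form,
  # and always stays inside [min, max] of the two correlations
  set.seed(42)
  for (i in 1:50) {
    vt <- runif(1, 0.1, 9)
    ve <- runif(1, 0.1, 9)
    rt <- runif(1)
    re <- runif(1, 0, 0.99)
    s0 <- condition_spec(vt, ve, tau_stability = rt)
    expect_identical(expected_trc_dependent(s0),
                     expected_trc(rt, reliability_from_variances(vt, ve)))
    s1 <- condition_spec(vt, ve, tau_stability = rt, error_dependence = re)
    v <- expected_trc_dependent(s1)
    expect_gte(v, min(rt, re))
    expect_lte(v, max(rt, re))
  }
})

test_that("dependent-error TRC is monotone in each correlation and in the ratio", {
  base <- condition_spec(5, 5, tau_stability = 0.5, error_dependence = 0.2)
  up_tau <- condition_spec(5, 5, tau_stability = 0.6, error_dependence = 0.2)
  up_eps <- condition_spec(5, 5, tau_stability = 0.5, error_dependence = 0.3)
  expect_gt(expected_trc_dependent(up_tau), expected_trc_dependent(base))
  expect_gt(expected_trc_dependent(up_eps), expected_trc_dependent(base))
  # raising the true-variance share raises the TRC iff stability exceeds
  # error dependence
  lo <- condition_spec(4, 6, tau_stability = 0.8, error_dependence = 0.2)
  hi <- condition_spec(6, 4, tau_stability = 0.8, error_dependence = 0.2)
  expect_gt(expected_trc_dependent(hi), expected_trc_dependent(lo))
  lo_rev <- condition_spec(4, 6, tau_stability = 0.2, error_dependence = 0.8)
  hi_rev <- condition_spec(6, 4, tau_stability = 0.2, error_dependence = 0.8)
  expect_lt(expected_trc_dependent(hi_rev), expected_trc_dependent(lo_rev))
})

test_that("closed forms are invariant to common variance rescaling", {
  for (c_scale in c(0.1, 3, 40)) {
    a <- condition_spec(9, 1, tau_stability = 0.7, error_dependence = 0.2)
    b <- condition_spec(9 * c_scale, 1 * c_scale, tau_stability = 0.7,
                        error_dependence = 0.2)
    expect_equal(reliability_from_variances(b), reliability_from_variances(a))
    expect_equal(expected_trc_dependent(b), expected_trc_dependent(a))
    expect_equal(trc_bias(b), trc_bias(a))
  }
})

test_that("bias equals reliability minus expected TRC", {
  expect_equal(trc_bias(spec_91(tau = 0.7)), 0.27)
  expect_equal(trc_bias(spec_91(tau = 0.8)), 0.18)
  expect_equal(trc_bias(condition_spec(3, 7, tau_stability = 1)), 0)
  # with independent errors the bias is (1 - stability) * reliability, and
  # it is non-negative whenever error dependence <= stability
  set.seed(7)
  for (i in 1:25) {
    rt <- runif(1)
    vt <- runif(1, 0.5, 9)
    ve <- runif(1, 0.5, 9)
    s <- condition_spec(vt, ve, tau_stability = rt)
    w <- reliability_from_variances(vt, ve)
    expect_equal(trc_bias(s), (1 - rt) * w)
    # attenuation dominates (bias >= 0) exactly when the error dependence
    # stays below w(1 - stability)/(1 - w); above it the TRC is inflated
    thr <- w * (1 - rt) / (1 - w)
    re_lo <- runif(1, 0, min(thr, 0.99))
    expect_gte(trc_bias(condition_spec(vt, ve, tau_stability = rt,
                                       error_dependence = re_lo)), 0)
    if (thr < 0.99) {
      re_hi <- runif(1, thr, 0.99)
      expect_lte(trc_bias(condition_spec(vt, ve, tau_stability = rt,
                                         error_dependence = re_hi)), 0)
    }
  }
  # dependent errors inflate the coefficient even under perfect stability
  expect_lt(trc_bias(condition_spec(9, 1, tau_stability = 1,
                                    error_dependence = 0.5)), 0)
})

test_that("reliability categories use inclusive .7/.8/.9 lower bounds", {
  got <- classify_reliability(c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7, 0.69, -0.2))
  expect_equal(as.character(got),
               c("excellent", "excellent", "good", "good", "acceptable",
                 "acceptable", "unacceptable", "unacceptable"))
  expect_true(is.ordered(got))
  expect_error(classify_reliability(1.5), "\\[-1, 1\\]")
})

test_that("condition specs enforce the measurement-model invariants", {
  expect_error(condition_spec(-1, 1), "non-negative")
  expect_error(condition_spec(0, 0), "total variance")
  expect_error(condition_spec(9, 1, tau_stability = -0.2), "\\[0, 1\\]")
  expect_error(condition_spec(9, 1, error_dependence = 1), "\\[0, 1\\)")
  s <- condition_spec(9, 1)
  expect_identical(s$error_mean, 0)
})

test_that("equivalence sets enumerate indistinguishable parameter triples", {
  eq <- equivalent_conditions(0.63, grid_resolution = 0.05, tolerance = 0.005)
  has <- function(m, rt, rel, re) {
    any(abs(m$tau_stability - rt) < 1e-9 & abs(m$reliability - rel) < 1e-9 &
          abs(m$error_dependence - re) < 1e-9)
  }
  expect_true(has(eq$members, 0.7, 0.9, 0))
  expect_true(has(eq$members, 0.9, 0.7, 0))
  expect_true(all(abs(eq$members$expected_trc - 0.63) <= 0.005))

  # a TRC near .60 is compatible with several reliability categories
  eq60 <- equivalent_conditions(0.60, grid_resolution = 0.05,
                                tolerance = 0.005)
  expect_gte(nrow(eq60$members), 2)
  expect_gte(length(unique(eq60$members$category)), 2)

  # a perfect TRC pins down perfect stability and reliability
  eq1 <- equivalent_conditions(1, grid_resolution = 0.25, tolerance = 0)
  expect_gt(nrow(eq1$members), 0)
  expect_true(all(eq1$members$tau_stability == 1))
  expect_true(all(eq1$members$reliability == 1))

  expect_error(equivalent_conditions(0.5, grid_resolution = 0), "\\(0, 1\\]")
  expect_error(equivalent_conditions(1.5), "\\[0, 1\\]")
})
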