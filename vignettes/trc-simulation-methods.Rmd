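---
title: "Simulating the test-retest coefficient under assumption violations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the test-retest coefficient under assumption violations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcsim)
```

## The measurement model

Classical test theory decomposes an observed score into a true score and an
error score, $x = \tau + \epsilon$, with $E(\epsilon) = 0$,
$\mathrm{Cov}(\tau, \epsilon) = 0$, and reliability defined as the
true-to-total variance ratio
$w = \sigma_\tau^2 / (\sigma_\tau^2 + \sigma_\epsilon^2)$. The test-retest
coefficient (TRC) is the Pearson correlation between observed scores from
two administrations, $r_{x_1 x_2}$. It equals $w$ only under two
assumptions: the trait is perfectly stable ($\tau_1 = \tau_2$) and the two
occasions' errors are independent.

`trcsim` studies what happens when those assumptions fail. Writing
$r_\tau = \mathrm{Corr}(\tau_1, \tau_2)$ for trait stability and
$r_\epsilon = \mathrm{Corr}(\epsilon_1, \epsilon_2)$ for systematic
(shared) error, equal component variances on both occasions give

$$
r_{x_1 x_2} \;=\; r_\tau\, w \;+\; r_\epsilon\, (1 - w),
$$

a convex combination of stability and error dependence weighted by each
component's share of total variance (`expected_trc_dependent()`). With
independent errors this is the attenuation product $r_\tau w$
(`expected_trc()`), and `trc_bias()` reports $w - r_{x_1 x_2}$: positive
when instability attenuates the coefficient below reliability, negative
when error dependence inflates it above.

```{r}
expected_trc(0.7, 0.9)                      # attenuation: .63
trc_bias(condition_spec(9, 1, tau_stability = 0.7))   # .27 underestimate
trc_bias(condition_spec(9, 1, tau_stability = 1,
                        error_dependence = 0.5))      # inflation
```

A consequence worth stating plainly: the sign condition for attenuation to
dominate is $r_\epsilon \le w(1 - r_\tau)/(1 - w)$, not
$r_\epsilon \le r_\tau$. Even a perfectly stable trait yields an inflated
coefficient as soon as any error dependence is present, because the
stability term is already at its ceiling.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `true_var`, `error_var` | variance components (score-units²) | — | set per condition; only their ratio matters (see below) |
| `tau_stability` | $r_\tau \in [0, 1]$ | 1 | the classical assumption; study grids sweep 1 down to .5 |
| `error_dependence` | $r_\epsilon \in [0, 1)$ | 0 | independent errors; .1/.3/.5 represent 1%/9%/25% shared error variance |
| `true_mean` | location of $\tau$ | 10 | a free location parameter, kept away from 0 so true and error scores are visibly distinct; no output depends on it |
| `reps` | replicates per condition | 1000 (full), 200 (desk) | the full count matches the study design; 200 keeps a desk run in minutes while leaving Monte Carlo SEs of means below ~0.002 |

Negative correlations are rejected: the model interprets stability and
error dependence as shared-signal proportions, and the study grids never
go below zero.

## The generator contract

`generate_scores()` draws standard-normal deviates, correlates them through
a factor of the 4×4 *correlation* matrix of $(\tau_1, \tau_2, \epsilon_1,
\epsilon_2)$ — Cholesky in the regular case, a symmetric eigendecomposition
when $r_\tau = 1$ makes the matrix singular — and only then scales by the
standard deviations and shifts by the means. Because the correlated
deviates never see the variances, multiplying both variances by a common
factor maps every score through an exact affine transformation of the same
deviates under a shared seed. This makes the scale-invariance finding —
TRC behaviour depends on the variances only through their ratio — a
structural property of the generator rather than an empirical observation.

One numerical nuance: with a zero location the invariance is exact at the
bit level (a power-of-two variance rescaling doubles every stored double
exactly, and Pearson's $r$ comes out bit-identical). With the default
nonzero location the final mean addition rounds at an absolute position
that does not scale, so replicate correlations agree across scales to
within one ulp ($\sim 2 \times 10^{-16}$) rather than bitwise. The tests
assert bit identity at mean zero and $10^{-13}$ agreement at mean 10.

`generate_fixed_tau()` realises perfect stability the way the study design
does: one true-score vector drawn and copied, so $\tau_1 = \tau_2$ holds
exactly rather than in distribution. A distributional-equivalence test
confirms it is interchangeable with `generate_scores()` at $r_\tau = 1$.

Degenerate settings are permitted: `error_var = 0` gives noise-free
observations (every replicate correlation is 1 and the stability SD is 0
up to rounding inside `cor()`); a zero-variance observed score would make
$r$ undefined, which `pearson_r()` signals as `NA` so the replication layer
can drop and count it rather than abort.

## Seeds and reproducibility

Each replicate gets its own child seed,
$(\text{root} + k \cdot 48271) \bmod (2^{31} - 1)$, and each condition in a
grid gets a child stream offset by $10^6$-scale condition indices. Results
are therefore reproducible cell-by-cell, a shorter run is a prefix of a
longer one, and replicate results do not depend on evaluation order.

## Monte Carlo summaries and stability criteria

`replicate_condition()` summarises replicate Pearson correlations by their
mean (accuracy) and standard deviation (coefficient stability), using the
$n - 1$ SD denominator and no Fisher-z transformation — raw correlations
are averaged, matching the simulation design being reproduced. Stability
thresholds are SD ≤ .05 ("good": roughly 68% of estimates within one
conventional reliability band) and SD ≤ .025 ("excellent": roughly 95%).
The analytic reference $(1 - \rho^2)/\sqrt{n - 1}$ (`sd_asymptotic()`) is
kept as an independent check; Monte Carlo SDs track it within 15% at
$n \ge 100$.

`min_sample_size()` locates the smallest sample size meeting a criterion by
a *sustained-crossing* rule: the criterion must hold at that grid point and
at every larger evaluated grid point. A single-crossing rule would be
fragile exactly where it matters — near the threshold the SD estimate
itself has ~2% relative noise at 1000 replicates — whereas sustained
crossing errs, if at all, toward recommending slightly larger samples. The
default grid spans 2–1000 (dense below 100, steps of 100 above 500),
bracketing every decision point of interest; searches that never sustain
the criterion report the 1000-participant ceiling rather than
extrapolating.

Two sample-size facts the closed form supports: excellent stability at
reliability .9 needs $n \approx 583$ when stability is .7 and
$n \approx 803$ when it is .6, which is why the searches return 600-ish and
800–900 on the default grid. At perfect stability and reliability .9 the
same formula gives $n \approx 59$ for the excellent criterion; a
requirement of "nearly 200" sometimes quoted for that cell is not
reconcilable with the sampling theory of $r$, and no output of this package
targets it.

## Reliability cutoffs

The conventional .70/.80/.90 interpretation bands are implemented with
*inclusive* lower bounds (a TRC of exactly .70 is "acceptable"). The
convention is usually stated as "around .7", which does not settle the
boundary; inclusivity makes `classify_reliability()` total and testable,
and no simulated quantity in the package lands on a boundary by
construction.

## Study grids and desk scale

`run_study1()` crosses stability {1, .9, .8, .7, .6, .5} with all 81
variance pairs from $\{1..9\}^2$ at 1000 replicates (full scale). The desk
scale keeps the four ratio-distinct pairs 9:1, 8:2, 7:3, 6:4 (reliability
.9/.8/.7/.6), a six-point $n$ grid {25, 50, 100, 200, 500, 1000}, and 200
replicates — the cells every reported quantity depends on — and completes
in well under a minute on one CPU. `run_study2()` crosses stability
{1, .9, .8, .7, .6} with error dependence {.1, .3, .5} over reliabilities
.60–.95 (step .05, full) or {.6, .7, .8, .9} (desk), realising each
reliability as variances $(10w, 10(1 - w))$; the total of 10 is arbitrary
by the scale-invariance property, and the generator contract makes that
provable rather than assumed. Study 2 runs its stability-1 level through
the correlated-normal path with $r_\tau = 1$ (the copied-vector path is
Study 1's construction); the equivalence test justifies treating the two
as interchangeable.

The underidentification explorer `equivalent_conditions()` enumerates a
uniform grid (default step .05, tolerance .005 — half a grid-step of the
expected-TRC surface's typical spacing) because the equivalence class of a
TRC value is a continuous surface; the enumeration is meant to exhibit
members spanning different reliability categories, not to parameterise the
surface. Estimating $r_\tau$, $r_\epsilon$, or $w$ from real two-wave data
is deliberately out of scope — the point of the explorer is that such
estimation is impossible.

## What the generator does and does not emulate

The synthetic scores are exactly jointly normal with equal variances across
occasions and no true-error covariance. Real test-retest data can be
skewed, ordinal, bounded (floor/ceiling effects induce $\tau$–$\epsilon$
covariance), and heteroscedastic across occasions. Passing tests therefore
show that the package reproduces the behaviour of the TRC *under the
best-case normal model*; they do not show that real instruments attain
these bias or sample-size figures, which are if anything optimistic for
non-normal data.

## Numerical choices

- Undefined replicate correlations are dropped and counted (`dropped`),
  with a warning; with variances ≥ 1 they cannot occur.
- $n = 2$ is admitted (the grids start there) but flagged when printed,
  since $r = \pm 1$ almost surely.
- Covariance factors: `chol()` with an eigendecomposition fallback,
  eigenvalues clipped at zero.
- Monte Carlo agreement tests allow $3\,\widehat{\mathrm{SD}}/\sqrt{R}$
  plus $10^{-3}$ for the $O(1/n)$ small-sample bias of $r$.
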