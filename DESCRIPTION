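Package: trcsim
Title: Monte Carlo Evaluation of the Test-Retest Reliability Coefficient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form theory and Monte Carlo simulation of the
    test-retest coefficient (TRC) under violations of classical-test-theory
    assumptions. Provides the expected TRC as the product of true-score
    stability and the true-to-total variance ratio, its generalisation to
    correlated (systematic) error scores as a variance-weighted sum, a
    joint-normal score generator with a reproducible scaling contract,
    replicate-level TRC summaries, minimum-sample-size searches against
    coefficient-stability criteria, bias tables, full and desk-scale
    simulation study grids, and an enumerator of observationally equivalent
    parameter combinations that illustrates the coefficient's
    underidentification from two-occasion data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
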