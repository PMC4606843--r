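Package: cronpower
Title: Power and Sample Size for Scale Scores of Parallel Questionnaire Items
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form statistical power, sample-size and item-count
    calculations for study designs whose outcome is the sum of parallel
    questionnaire items with a given Cronbach alpha. Under a
    compound-symmetry (essentially tau-equivalent) measurement-error model
    with fixed true-score variance, Cronbach alpha equals both the
    reliability and the test-retest correlation of the scale score, and the
    power of pre-post, between-group within-group, and two-sample
    comparisons -- as well as of the significance test of alpha itself via
    the Fisher z-transformation -- can be written explicitly in terms of
    alpha. The package provides these power functions and their sample-size
    and item-count inverses, a simulator of parallel-item data for the four
    designs, and a Monte Carlo engine estimating empirical power and
    empirical test-retest correlation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
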