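Package: tvarace
Title: Fixed-Capacity Race Modeling of Whole and Partial Report
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact likelihoods and maximum-likelihood fitting for the
    fixed-capacity independent race model of visual attention (TVA) applied
    to whole and partial report of briefly presented graphemes. Provides the
    exact report-set likelihood (exponential processing races, normally
    distributed perceptual threshold, a free capacity distribution over
    visual short-term memory, spatial attentional weights and a lapse rate),
    per-observer 15-parameter fits, a generative synthetic-observer
    simulator matching a 9-pair synesthete/control design, grapheme-color
    consistency screening statistics, and paired congruence-contrast
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    pracma,
    rlang,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
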