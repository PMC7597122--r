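Package: ecatradeoff
Title: Universality-Efficiency Trade-Off in Elementary Cellular Automata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies computational universality (the normalized number of
    reachable states) and computational efficiency (the mean transient time to
    reach them, with a timeout penalty) for all 256 elementary cellular automaton
    rules under synchronous and probabilistically asynchronous updating. Builds
    the lower-margin step frontier of the (universality, efficiency) cloud,
    measures the degree to which asynchronous updating breaks the synchronous
    trade-off, segments one-step asynchronous transitions into stretches each
    explainable by a single synchronously applied "apparent" rule, emulates
    asynchronous dynamics with synchronous multi-rule updating, and sweeps
    segment and rule counts over the asynchrony probability with polynomial
    fits. All simulations are seeded and reproducible; tabular results are
    returned as tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    readr,
    jsonlite,
    generics,
    rlang,
    withr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
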