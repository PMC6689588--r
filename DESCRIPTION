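Package: skewlearn
Title: Agent-Based Simulation of Reproductive Skew and the Evolution of
    Social Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates foraging populations in which individuals acquire
    information about gamma-distributed resource patches either by
    individual sampling or by copying previous-round foragers, compete by
    exploitative scramble, and reproduce under adjustable reproductive
    skew (the top-ranked proportion of foragers, by a temporally
    discounted payoff window, is eligible to breed). Supports
    fixed-composition populations, asexual evolutionary runs, and
    sexually reproducing populations with sex-linked inheritance and
    sex-specific skew. Provides seeded replicate runs, parameter sweeps
    over skew, environmental turnover and resource variance, and summary
    statistics of strategy-wise yield variability and evolved
    social-learning frequencies. The round update is implemented in C++
    for full-scale runs; a pure-R reference engine exposes every model
    operation for inspection and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
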