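Package: ccitnet
Title: Gene Regulatory Network Inference with Combined Conditional
    Independence Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure learning for gene regulatory networks in which
    instantaneous (same time slice) and multi-step time-delayed
    regulations are represented and scored simultaneously.  A single
    delay-annotated network holds both arc kinds; each gene is scored
    against the union of its parents across all lags with a
    mutual-information statistic penalized by per-lag-class chi-squared
    critical values (the CCIT score).  The package provides the score
    and its MIT-family baselines, greedy hill-climbing search with an
    exhaustive oracle, a discrete time-series simulator with binomial,
    noisy-XOR and Dirichlet conditional distributions, equal-frequency
    discretization, and confusion-matrix evaluation against a ground
    truth network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
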