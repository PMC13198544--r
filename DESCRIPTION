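Package: wholereport
Title: Mixture Modelling of Multifeature Whole-Report Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a hierarchical Bayesian mixture model of
    continuous-report visual short-term memory in which observers reproduce
    both the colour and the location of three memorised objects in a freely
    chosen order.  The per-trial likelihood marginalises over latent report
    orders, symmetric swap and cyclic-swap errors, and feature/object
    guessing states, which lets misbinding errors be decomposed into
    symmetric misbinding and asymmetric misattribution.  Also provides WAIC
    model comparison across model variants, default-prior (JZS) Bayes-factor
    tests, and Loftus-Masson within-subject standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
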