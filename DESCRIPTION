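Package: connbench
Title: Multi-Scale Statistical Inference and Power Benchmarking for
    Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical inference for paired task-versus-rest functional
    connectivity studies at four spatial scales: individual edges
    (Bonferroni or Storey false discovery rate control), clusters of
    contiguous edges (network-based statistic and threshold-free cluster
    enhancement with max-statistic permutation correction), predefined
    large-scale networks (pooled network statistics with Bonferroni or
    Simes correction over permutation nulls), and the whole brain (a
    multivariate omnibus test on the pooled-network statistic vector).
    Includes an empirical benchmarking harness that resamples subject
    groups from a population, classifies sign-matched true and false
    positives against a full-sample ground truth, and reports power,
    false discovery rate, spatial extent and precision of false
    positives, and strong- and weak-sense familywise error rates, plus a
    synthetic generator of paired task/rest connectome populations with
    community structure for fully reproducible evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
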