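Package: retroinfer
Title: Finite Retrospective Inference in Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Online fixed-lag variational smoothing in discrete hidden Markov
    models with simultaneous Dirichlet parameter learning ("finite
    retrospective inference").  Provides an exact scaled forward-backward
    engine, variational Bayes dual estimation with Dirichlet beliefs over
    transition and emission matrices, a sliding-window agent that revises
    beliefs about a bounded number of past states as each observation
    arrives, seeded generators for the two-state probabilistic reversal
    task and for random three-state HMMs, and the accuracy metrics and
    simulation studies that quantify how retrospection depth improves
    state inference and parameter learning.
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
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
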