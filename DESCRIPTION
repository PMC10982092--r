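Package: gacovsel
Title: Genetic-Algorithm Covariate Selection for Population PK Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic covariate selection for population (nonlinear
    mixed-effects) pharmacokinetic models by a genetic algorithm over
    binary-encoded covariate models. Candidate parameter-covariate
    relationships (linear, exponential, piece-wise linear, power;
    linear for categorical covariates) are encoded as fixed-length bit
    strings; fitness penalizes the objective function value by a
    chi-square weight per covariate coefficient and by the pairwise
    correlation of continuous covariates included on the same
    parameter. Includes hierarchical-clustering population
    initialization on Jaccard distances, tournament selection,
    single-point crossover, single-bit mutation, elitism, an
    evaluated-model cache and a 95th-percentile runtime timeout
    heuristic; an internal first-order (FO) estimator for the
    one-compartment intravenous model; an NM-TRAN control-stream
    writer; a stepwise covariate modeling (SCM) comparator; and a
    simulator for a covariate-rich evaluation study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    parallel,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
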