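Package: moultphen
Title: Individual Moult Phenology from Longitudinal Resighting Data
Version: 0.1.0
Authors@R: person("Ano Nuevo", "Phenology Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating individual-level moult phenology from
    longitudinal resighting tables of marked animals. Fits a hierarchical
    Bayesian logistic model of moult progression (adaptive
    Metropolis-within-Gibbs, Rcpp backend) and derives per-cycle moult start,
    midpoint, end and duration with credible intervals; estimates
    detection-corrected haul-out arrival and departure dates; computes
    population occupancy and moulting curves, peak synchrony and population
    event windows; partitions variance in moult metrics between age-sex
    category, year and individual with gamma mixed models; and includes a
    seeded synthetic-colony generator that emulates the survey and scoring
    process so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    digest,
    lme4,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
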