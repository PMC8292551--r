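Package: msceoac
Title: Multistage Clonal Expansion Modelling of Oesophageal Adenocarcinoma via Barrett's Oesophagus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and stochastic implementations of the multistage clonal
    expansion (MSCE) model of oesophageal adenocarcinoma (OAC) arising through
    Barrett's oesophagus (BE). Solves the backward survival equations of the
    post-BE clonal expansion process to obtain age-specific OAC hazards,
    models GERD-stratified BE onset and prevalence, calibrates rate parameters
    to registry-style incidence tables by Poisson maximum likelihood with
    likelihood-ratio model selection, and projects expected annual case
    counts, BE carrier numbers and BE-to-OAC progression rates onto
    census-style person-year tables. An exact event-driven (Gillespie)
    microsimulator with identical model semantics serves as an independent
    oracle, and synthetic-data generators emulate registry, census and
    screening-yield inputs so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
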