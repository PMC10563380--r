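Package: locrm
Title: Local Continual Reassessment Designs for Drug-Combination Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bayesian adaptive designs for early-phase drug-combination
    trials based on local continual reassessment. Implements the LOCRM
    design for locating the maximum tolerated dose combination from
    toxicity data, and the two-stage LOCRM12 design for optimizing the
    biological dose combination from toxicity and efficacy jointly.
    Includes enumeration of local partial toxicity orderings, Bayesian
    model averaging over the empiric one-parameter CRM model, robit
    (Student-t link) efficacy regression with adaptive MCMC, weighted
    bivariate isotonic regression for end-of-trial estimation,
    beta-binomial overdose and futility monitoring, bundled simulation
    scenarios, and a replication engine for operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
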