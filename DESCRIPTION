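Package: echotrial
Title: Screening, Cluster Randomization, and Win-Ratio Power Simulation
    for Valve-Disease Notification Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational machinery for a provider-cluster-randomized trial
    of automated echocardiogram-based notifications in severe aortic stenosis
    and moderate-to-severe or severe mitral regurgitation.  Provides a
    deterministic eligibility rule engine over echocardiographic measurements,
    recipient assignment and two-tranche stratified 1:1 provider
    randomization, a synthetic trial generator with exponential margins
    joined by a Gumbel-Hougaard copula and calibrated 90-day incidences, the
    stratified win-ratio analysis of the hierarchical composite endpoint
    (closed-form large-sample inference and a provider-cluster bootstrap),
    and Monte-Carlo power and type-I-error simulation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
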