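Package: ecdtrial
Title: Design, Simulation and Analysis of Cluster-Randomised Early Child
    Development Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for three-arm cluster-randomised trials of early child
    development interventions: scoring of field instruments (Family Care
    Indicators, Ages and Stages Questionnaire inventory, Communicative
    Development Inventories, CES-D, minimum dietary diversity), internal
    age-standardisation of development scores to the control arm,
    intention-to-treat effect estimation by parametric g-computation with
    village-clustered bootstrap confidence intervals, likelihood-ratio
    covariate prescreening, pooled-SD effect sizes, cluster-design power
    and sample-size calculations, stratified randomisation, and
    CONSORT-style flow accounting.  A synthetic trial generator with
    village random intercepts reproduces the data structure the analysis
    assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lmtest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
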