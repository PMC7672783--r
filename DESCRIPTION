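Package: sdmcea
Title: Cost-Effectiveness Modelling of Shared Decision Making for
    Disease-Modifying Drug Choice in Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An EDSS-based cohort state-transition model for relapsing-remitting
    multiple sclerosis with treatment sequencing, real-world discontinuation,
    adherence mixing and Dutch-style cost and QALY accounting, used to compare
    shared decision making with usual care for choosing between
    disease-modifying drugs. Provides deterministic, one-way, threshold and
    probabilistic cost-effectiveness analyses, a seeded synthetic parameter
    generator, and an individual-level microsimulation oracle for engine
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
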