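Package: psadapt
Title: PSA-Guided Adaptive Therapy Dynamics in Metastatic
    Castrate-Resistant Prostate Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the eco-evolutionary dynamics of three competing
    prostate-cancer cell types (testosterone-dependent, testosterone-
    producing, testosterone-independent) under abiraterone therapy using a
    Lotka-Volterra competition model with treatment-dependent carrying
    capacities. Prostate-specific antigen (PSA) is modelled as a weighted
    combination of the three subpopulations, and PSA-guided adaptive
    therapy (treatment off at 50% of baseline PSA, on again at baseline)
    is compared with continuous maximum tolerable dose via the time to
    competitive release of the resistant clone. Includes the three
    representative patient presets (best responder, responder,
    non-responder), sensitivity scans over the PSA production weights, and
    a virtual-patient cohort generator with equilibrium-based response
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
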