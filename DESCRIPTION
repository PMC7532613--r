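Package: scrisk
Title: Secondary Cancer Risk Estimation from Dose-Volume Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating radiation-induced secondary cancer risk
    after external-beam radiotherapy. Computes organ equivalent dose (OED)
    from differential or cumulative dose-volume histograms under linear,
    linear-exponential and linear-plateau dose-response models, converts
    OED to excess absolute risk (EAR) using age-dependent baseline
    coefficients derived from atomic-bomb survivor cohorts, and compares
    treatment techniques (e.g. pencil-beam-scanning proton therapy versus
    tangential 3D-CRT or VMAT) at cohort level with paired significance
    tests. Includes a calibrated synthetic DVH cohort generator so the
    full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
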