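Package: cephsweep
Title: Occlusal-Plane Rotation Sensitivity of Facial Aesthetic Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how rotating the occlusal plane (the SN-OP angle)
    changes two cephalometric aesthetic indices, the posterior-anterior
    face height ratio (FHR) and the facial angle (FA), across nine
    sagittal-by-vertical skeletal types. Provides a calibrated synthetic
    cohort generator, rule-based skeletal classification, feedforward
    neural surrogate models with min-max normalization and early
    stopping, a per-patient counterfactual SN-OP sweep with ordinary
    least-squares slope extraction, and the accompanying statistical
    layer (normality screening, ANOVA/Kruskal-Wallis group comparison
    with Bonferroni or Dunn post-hoc correction, Bland-Altman agreement,
    and intraclass correlation reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    jsonlite,
    yaml,
    nortest,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
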