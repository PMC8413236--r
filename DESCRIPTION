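Package: ppfequant
Title: Computerised Quantification of Pleuroparenchymal Fibroelastosis on CT
    with Prognostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the extent of pleuroparenchymal fibroelastosis (PPFE)
    on thoracic CT as the percentage of the upper-zone visceral pleural
    surface occupied by dense subpleural tissue (cPPFE), and carries the
    score through the downstream prognostic analyses used in idiopathic
    pulmonary fibrosis cohorts: radiologist lobar PPFE scoring, linear
    mixed-effects prediction of 1-year forced vital capacity decline,
    Cox and frailty Cox survival models with concordance bootstrapping,
    Kaplan-Meier medians with Dorey-Korn confidence intervals, fixed-horizon
    classification metrics under censoring, and DeLong ROC comparisons.
    Includes generators for CT lung phantoms with known pleural lesion
    coverage and for synthetic cohorts with known trajectory and hazard
    parameters, so that every stage is testable against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    lme4,
    lmerTest,
    survival,
    pROC,
    lmtest,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
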