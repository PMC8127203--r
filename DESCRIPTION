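Package: CaseLoDA
Title: Model-Based Dynamic Case Ascertainment from Administrative Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing and validating chronic disease case
    definitions from administrative health data (physician claims and
    hospital discharge abstracts), with juvenile arthritis as the worked
    disease setting. Implements longitudinal discriminant analysis based on
    group-specific multivariate generalized linear mixed models fitted by
    Markov chain Monte Carlo, dynamic classification of individuals into
    case, control, and indeterminate categories using credible-interval
    allocation with an ROC-optimal cutoff, a validated deterministic
    ICD-coded case definition with restricted-window sensitivity analyses,
    a claim-level synthetic cohort generator that emulates the linked
    registry/claims structure the methods assume, and five-fold
    cross-validated accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
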