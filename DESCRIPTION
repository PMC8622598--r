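Package: cmax3
Title: Covariate-Adjusted MAX3 Robust Test for Genetic Association
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Robust single-marker association testing for case-control studies
    when the genetic model (recessive, additive or dominant) is unknown.
    Implements per-model score tests from logistic regression with nuisance
    covariates, the covariate-adjusted MAX3 statistic (the maximum of the three
    absolute score statistics), its joint null correlation structure, and an
    asymptotic p-value computed as a trivariate-normal rectangle probability.
    Includes the 2-df likelihood ratio test and the classical covariate-free
    MAX3 as comparators, a retrospective case-control simulation engine for
    operating-characteristic studies, and single-SNP and batch command-line
    entry points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
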