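Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance analysis toolkit for FDA Adverse
    Event Reporting System (FAERS) style spontaneous reporting data:
    parsing of the quarterly '$'-delimited ASCII tables, case-version
    deduplication, cohort selection with co-medication exclusion, 2x2
    contingency construction at the MedDRA preferred-term and system-organ-class
    levels, four disproportionality estimators (reporting odds ratio,
    proportional reporting ratio with chi-square, Bayesian confidence
    propagation neural network information component, and the multi-item
    gamma Poisson shrinker), Weibull time-to-onset modelling with failure-type
    classification, and a synthetic spontaneous-reporting-system generator
    with planted signals of known relative risk so that every stage is
    testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    yaml
Config/testthat/edition: 3
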