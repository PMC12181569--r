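Package: senoscan
Title: Senescence-Signature Prognostic Scanning for Merged Microarray Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostic analysis of a senescence-associated gene
    signature (SenMayo-style mean expression score) in merged MAS5-normalized
    breast cancer microarray cohorts. Provides secondary scaling normalization
    to a common shared-probe mean, duplicate-sample removal, a five-parameter
    array quality-control filter, expression-surrogate estrogen/HER2 receptor
    calls with St Gallen subtype assignment, signature scoring, a
    quartile-bounded minimum-p survival cutoff scan with hazard-ratio
    tie-breaking and Benjamini-Hochberg false discovery rate control, paired
    multivariate Cox models, and a synthetic-cohort generator with ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
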