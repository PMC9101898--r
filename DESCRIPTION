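Package: ocdsig
Title: Ovarian Cancer Stem-Cell Differentiation Methylation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving prognostic DNA-methylation gene signatures
    from a staged cancer stem-cell differentiation methylome and
    transcriptome. Implements promoter-window definition and sample QC,
    three-phase differential methylation/expression integration with
    negative-correlation candidate selection, the recurrent risk score
    (RRS): a signed vote count over five quantile cutoffs and three
    progression-free-survival endpoints evaluated in two independent
    cohorts, risk-count signature stratification with Kaplan-Meier,
    log-rank and Cox proportional-hazards evaluation, and
    immune-infiltration correlation with joint-stratum survival analysis.
    A synthetic-data module simulates stage omics matrices, paired
    survival cohorts with planted proportional-hazards effects, and
    immune profiles, so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
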