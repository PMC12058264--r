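Package: radiotox
Title: Polygenic Risk Scores and Radiotherapy Toxicity Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether germline genetic predisposition,
    summarised as a polygenic risk score computed from imputed genotype
    dosages, associates with acute and late normal-tissue toxicity after
    curative-intent radiotherapy. Implements risk-allele harmonization of
    dosage data, unweighted and odds-ratio-weighted score computation,
    Standardized Total Average Toxicity (STAT) scoring of longitudinal CTCAE
    grade records, biologically effective dose conversion, and a per-site
    univariable/multivariable linear-regression association battery with
    Bonferroni control over endpoint families. A synthetic-cohort generator
    (Hardy-Weinberg genotypes, per-site covariates, right-skewed ordinal
    toxicity with an optional planted genetic effect) makes every stage
    testable end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
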