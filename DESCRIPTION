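Package: sigfalsify
Title: Falsification of Prognostic Gene-Expression Signatures via
    GO-Disjoint Surrogate Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether a prognostic gene-expression signature carries
    biological meaning beyond predictive utility. Implements a gene removal
    procedure that constructs surrogate ("random") gene sets sharing zero
    Gene Ontology biological-process terms with the signature, evaluates
    each surrogate's prognostic performance by first-principal-component
    patient stratification followed by a Kaplan-Meier / Mantel-Haenszel
    (log-rank) comparison, and reports Bonferroni-corrected significance
    across B resamples. Includes readers for expression matrices, clinical
    survival tables, GMT signatures, GAF/TSV annotation and OBO ontologies,
    plus a fully synthetic cohort generator with controllable prognostic
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
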