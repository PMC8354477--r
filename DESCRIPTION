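Package: delmeta
Title: Integrative Rare CNV Deletion and De Novo Variant Burden Meta-Analysis
Version: 0.1.0
Authors@R:
    person("delmeta", "maintainers", email = "delmeta@example.org",
           role = c("aut", "cre"))
Description: Gene-wise integration of two streams of rare-variant evidence for
    dosage-sensitive disease genes, as used in congenital heart disease
    case-control meta-analyses. Implements quality control and internal
    frequency filtering of copy-number deletion calls, gene- and region-wise
    label-permutation burden tests with pointwise (EMP1) and family-wise
    min-p (EMP2) empirical p-values, covariate-adjusted logistic gene-set
    burden tests, de novo variant classification and Poisson recurrence
    testing against per-gene mutation rates, Fisher combination of the two
    evidence streams with a covariate-weighted (LOEUF) Bonferroni correction,
    developmental-stage expression ranking and time-course differential
    expression, seed-restricted protein-interaction sub-cluster detection,
    and seeded synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
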