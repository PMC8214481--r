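Package: herbnet
Title: Mining Core and Disease-Specific Herbs from Prescription Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable pipeline for distilling core and disease-specific herb
    combinations from cohort-labelled prescription transactions and for
    characterising their molecular mechanisms. Builds weighted co-prescription
    networks and extracts main-herb shells with a degree-coefficient criterion,
    screens disease-specific herbs by relative risk with chi-square tests,
    mines association rules with a from-scratch Apriori implementation,
    detects dense protein-interaction cores (MCODE), ranks compounds by random
    walk with restart from disease-gene seeds, performs hypergeometric
    gene-set over-representation with Benjamini-Hochberg correction, and
    clusters binary herb-by-feature profiles with Ward linkage on the error
    sum of squares. A synthetic-data module generates cohorts and molecular
    networks with planted structure so every stage is testable without access
    to hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
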