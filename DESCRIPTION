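Package: mirgs
Title: miRNA Gene-Set Enrichment by Logistic Regression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfers microRNA differential-expression evidence onto target
    mRNAs as a signed quantitative impact score, then tests each gene set for
    miRNA-dependent regulation with a per-set univariate logistic regression
    (membership on score), reporting signed coefficients and FDR-adjusted Wald
    p-values. Includes readers and writers for the standard input formats
    (differential-expression CSV, GMT gene sets, miRNA:mRNA interaction tables,
    ortholog maps), local-table target mapping with human-ortholog Entrez
    conversion, volcano and bar visualisations, and a synthetic-data generator
    with planted enrichment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, Matrix
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
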