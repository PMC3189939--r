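Package: cafet
Title: Sample-Axis Pathway Enrichment for Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coverage Analysis with Fisher's Exact Test (CAFET): pathway
    enrichment along the sample axis of an expression cohort. A sample carries a
    pathway signature when at least one member gene is dysregulated relative to
    its per-probe median, and the concentration of signature-carrying samples in
    a sample group of interest is scored with the one-sided hypergeometric upper
    tail. Includes the conventional gene-axis over-representation baseline (FGA),
    probe filtering, log transformation, Welch-t differential expression with
    Benjamini-Hochberg control, average-linkage sample clustering, a per-sample
    signature score, readers for GMT, gene2go and flat KEGG gene-set formats, a
    seeded generator of microarray-like cohorts with planted concentrated or
    distributed dysregulation, and a command-line interface.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
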