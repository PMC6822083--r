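Package: oncoutlier
Title: Comparative Tumor Gene Expression Outlier Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-sample gene expression outlier detection for precision
    oncology. Compares one focus tumor's TPM profile against a large reference
    compendium using Tukey upper fences on log2(TPM+1), in a pan-cancer track
    (whole compendium, filtered gene universe) and a pan-disease track
    (most-similar tumors, full gene universe). Outlier gene lists are
    intersected with a curated actionable-gene table, annotated with offline
    drug-gene interactions, tested for gene-set overlap with hypergeometric
    enrichment under Benjamini-Hochberg FDR control, and combined with DNA
    mutation findings into a DNA-vs-RNA concordance classification. Includes a
    seeded synthetic-data generator that emulates a tumor compendium, spiked
    focus samples, and paired DNA findings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
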