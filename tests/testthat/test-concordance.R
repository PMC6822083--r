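dna_row <- function(sample_id, gene, dna_actionable = TRUE,
                    allele_expressed = NA, downstream = "") {
  tibble::tibble(
    sample_id = sample_id, gene = gene, variant = "p.X1Y",
    variant_class = "SNV", dna_actionable = dna_actionable,
    rna_mutant_allele_expressed = allele_expressed,
    downstream_groups = downstream
  )
}

rna_row <- function(sample_id, symbol, group = "RTK") {
  tibble::tibble(
    sample_id = sample_id, symbol = symbol, class = "direct",
    pathway_group = group, tracks = "pan_cancer", drugs = "", n_drugs = 0L
  )
}

no_rna <- rna_row("S", "X")[0, ]

test_that("expression support grades gene-level, downstream, none", {
  expect_identical(
    expression_support_check("FLT3", "RTK", outlier_genes = "FLT3",
                             enriched_groups = character(0)),
    "gene_level"
  )
  # activating RAS mutation with downstream proliferation programs enriched
  expect_identical(
    expression_support_check("NRAS", "cell-cycle;BCL2-MDM2;RAS-RAF-MEK",
                             outlier_genes = "FLT3",
                             enriched_groups = c("cell-cycle", "BCL2-MDM2")),
    "downstream"
  )
  expect_identical(
    expression_support_check("BRAF", "", outlier_genes = character(0),
                             enriched_groups = character(0)),
    "none"
  )
  # no mapping row means no downstream support can be claimed
  expect_identical(
    expression_support_check("CSF1R", character(0), character(0), c("RTK", "SHH")),
    "none"
  )
})

test_that("classification reproduces the canonical case patterns", {
  # mutation not expressed in the RNA, no downstream support -> deprioritize
  rec <- classify_sample(
    dna_row("S1", "BRAF", allele_expressed = FALSE, downstream = "RAS-RAF-MEK"),
    no_rna, enriched = character(0)
  )
  expect_identical(rec$venn_cell, "dna_only")
  expect_identical(rec$utility_mode, "deprioritize")

  # fusion with its downstream pathway enriched -> support
  rec2 <- classify_sample(
    dna_row("S2", "BCR-ABL1", downstream = "PI3K-AKT-mTOR;BCR"),
    rna_row("S2", "FLT3"), enriched = "PI3K-AKT-mTOR"
  )
  expect_identical(rec2$venn_cell, "both")
  expect_identical(rec2$utility_mode, "support")
  expect_match(rec2$evidence, "downstream:BCR-ABL1")

  # nothing on either side
  rec3 <- classify_sample(dna_row("S3", "X")[0, ], no_rna)
  expect_identical(rec3$venn_cell, "neither")
  expect_identical(rec3$utility_mode, "none")

  # several actionable DNA genes, one with gene-level support -> prioritize
  rec4 <- classify_sample(
    dplyr::bind_rows(dna_row("S4", "FLT3"), dna_row("S4", "KRAS")),
    rna_row("S4", "FLT3"), enriched = character(0)
  )
  expect_identical(rec4$utility_mode, "prioritize")

  # RNA findings with no DNA findings <=> rna_only mode
  rec5 <- classify_sample(dna_row("S5", "X")[0, ], rna_row("S5", "BTK"))
  expect_identical(rec5$venn_cell, "rna_only")
  expect_identical(rec5$utility_mode, "rna_only")

  # unknown allele expression is never deprioritized
  rec6 <- classify_sample(dna_row("S6", "TP53", allele_expressed = NA), no_rna)
  expect_identical(rec6$utility_mode, "none")

  # non-actionable DNA findings do not raise the DNA flag
  rec7 <- classify_sample(dna_row("S7", "TTN", dna_actionable = FALSE),
                          rna_row("S7", "BTK"))
  expect_identical(rec7$venn_cell, "rna_only")

  expect_error(
    classify_sample(dna_row("S8", "X"), rna_row("S9", "BTK")),
    "conflicting", class = "oncoutlier_input_error"
  )
})

test_that("venn cells partition every classified cohort", {
  set.seed(41)
  for (r in 1:10) {
    n <- 30L
    recs <- purrr::map_dfr(seq_len(n), function(i) {
      dna <- if (runif(1) < 0.5) dna_row(paste0("S", i), "FLT3") else dna_row("x", "y")[0, ]
      rna <- if (runif(1) < 0.5) rna_row(paste0("S", i), "BTK") else no_rna
      classify_sample(dna, rna, sample_id = paste0("S", i))
    })
    expect_identical(nrow(recs), n)
    expect_true(all(recs$venn_cell %in% c("both", "dna_only", "rna_only", "neither")))
    expect_true(all(
      (recs$venn_cell == "both") == (recs$dna_flag & recs$rna_flag),
      (recs$venn_cell == "rna_only") == (recs$utility_mode == "rna_only")
    ))
    summ <- summarize_cohort(recs)
    cells <- summ$count[summ$metric %in% c("both", "dna_only", "rna_only", "neither")]
    expect_identical(sum(cells), n)
  }
})

test_that("cohort summary reproduces one-decimal half-up percentages", {
  recs <- tibble::tibble(
    venn_cell = rep(c("both", "dna_only", "rna_only", "neither"), c(28, 6, 27, 13))
  )
  summ <- summarize_cohort(recs)
  expect_identical(attr(summ, "n_total"), 74L)
  got <- setNames(summ$percent, summ$metric)
  expect_identical(got[["both"]], 37.8)
  expect_identical(got[["dna_only"]], 8.1)
  expect_identical(got[["rna_only"]], 36.5)
  expect_identical(got[["neither"]], 17.6)
  expect_identical(got[["dna_actionable"]], 45.9)  # 34 of 74
  expect_identical(got[["rna_actionable"]], 74.3)  # 55 of 74
  counts <- setNames(summ$count, summ$metric)
  expect_identical(counts[["dna_actionable"]], 34L)
  expect_identical(counts[["rna_actionable"]], 55L)

  # exact .5 remainders round up, not to even
  summ2 <- summarize_cohort(tibble::tibble(
    venn_cell = rep(c("rna_only", "neither"), c(99, 45))
  ))
  expect_identical(summ2$percent[summ2$metric == "rna_only"], 68.8) # 99/144

  one <- summarize_cohort(tibble::tibble(venn_cell = "both"))
  expect_identical(one$percent[one$metric == "both"], 100)
  expect_identical(one$percent[one$metric == "rna_actionable"], 100)

  expect_error(summarize_cohort(recs[0, ]), class = "oncoutlier_input_error")
  expect_error(summarize_cohort(tibble::tibble(venn_cell = "odd")),
               class = "oncoutlier_input_error")
})

test_that("cohort summary is permutation-invariant", {
  set.seed(2)
  recs <- tibble::tibble(
    venn_cell = sample(rep(c("both", "dna_only", "rna_only", "neither"), c(5, 3, 7, 2)))
  )
  a <- summarize_cohort(recs)
  b <- summarize_cohort(recs[sample(nrow(recs)), , drop = FALSE])
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("rounding helper follows the half-up convention", {
  expect_identical(round_half_up(c(68.75, 37.837, 8.108, 17.568), 1),
                   c(68.8, 37.8, 8.1, 17.6))
  expect_identical(round_half_up(2.5, 0), 3)
  expect_identical(round_half_up(-2.45, 1), -2.5)
  expect_identical(round_half_up(100 * 1859 / 11340, 1), 16.4)
})
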