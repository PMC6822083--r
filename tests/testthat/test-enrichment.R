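test_that("hypergeometric tail matches enumeration and the edge identities", {
  expect_equal(hypergeom_overlap_p(0, 3, 4, 10), 1) # P(X >= 0) = 1
  # list = universe forces overlap = set size, and P(X >= s) = 1
  expect_equal(hypergeom_overlap_p(4, 10, 4, 10), 1)
  expect_equal(
    hypergeom_overlap_p(2, 3, 4, 10),
    oracle_hyper_upper(2, 3, 4, 10)
  )
  expect_error(hypergeom_overlap_p(5, 3, 4, 10), class = "oncoutlier_input_error")
  expect_error(hypergeom_overlap_p(0, 3, 11, 10), class = "oncoutlier_input_error")
  # overlap below the margin-forced minimum is inconsistent
  expect_error(hypergeom_overlap_p(0, 9, 9, 10), class = "oncoutlier_input_error")
})

test_that("BH adjustment matches the hand step-up and base identities", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "oncoutlier_input_error")
})

test_that("BH is permutation-equivariant", {
  set.seed(3)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("enrich reports significant sets sorted, ranked and truncated", {
  universe <- sprintf("U%04d", 1:1000)
  the_list <- universe[1:30]
  collection <- gene_set_collection(
    c(
      list(HIT_SET = c(universe[1:20], universe[101:130])), # 20 of 30 list genes
      purrr::map(setNames(1:10, sprintf("BG_%02d", 1:10)),
                 function(i) universe[(300 + i * 20):(319 + i * 20)])
    ),
    universe_size = 1000
  )
  res <- enrich(the_list, collection, universe = universe)
  expect_identical(res$set_name[1], "HIT_SET")
  expect_equal(
    res$p_value[1],
    hypergeom_overlap_p(20, 30, 50, 1000)
  )
  expect_identical(res$rank, seq_len(nrow(res)))

  # disjoint list: nothing significant
  none <- enrich(universe[900:910], collection, universe = universe)
  expect_identical(nrow(none), 0L)

  # 150 copies of the list itself: all significant, capped at 100
  many <- gene_set_collection(
    purrr::map(setNames(1:150, sprintf("SAME_%03d", 1:150)), function(i) the_list),
    universe_size = 1000
  )
  res_many <- enrich(the_list, many, universe = universe)
  expect_identical(nrow(res_many), 100L)
  expect_identical(res_many$set_name, sort(res_many$set_name))

  # genes outside the universe are dropped and counted
  res_drop <- enrich(c(the_list, "NOT_A_GENE"), collection, universe = universe)
  expect_identical(attr(res_drop, "n_dropped"), 1L)
  expect_identical(res_drop$list_size[1], 30L)
})

test_that("enrichment of an empty list or empty collection is empty", {
  coll <- gene_set_collection(list(A = c("G1", "G2")))
  expect_identical(nrow(enrich(character(0), coll)), 0L)
  expect_identical(nrow(enrich("G1", gene_set_collection(list()))), 0L)
})

test_that("pathway summary combines gene and set evidence per group", {
  act <- synthetic_actionable_genes()
  pmap <- synthetic_pathway_map(act)
  findings <- intersect_actionable(
    structure(list(pan_cancer = c("FLT3", "FGFR1"), pan_disease = character(0),
                   intersection = character(0), sample_id = "S1"),
              class = "outlier_lists"),
    act
  )
  enr <- structure(
    tibble::tibble(set_name = "SYNTHETIC_RTK_SIGNALING"),
    class = c("enrichment_result", class(tibble::tibble()))
  )
  summ <- pathway_outlier_summary(findings, enr, pmap)
  rtk <- summ[summ$pathway_group == "RTK", ]
  expect_true(rtk$gene_outlier && rtk$set_enriched && rtk$both)
  shh <- summ[summ$pathway_group == "SHH", ]
  expect_false(shh$gene_outlier)
  expect_false(shh$set_enriched)
  expect_identical(enriched_groups(summ), "RTK")

  # gene outlier without enrichment
  summ2 <- pathway_outlier_summary(findings, enr[0, ], pmap)
  rtk2 <- summ2[summ2$pathway_group == "RTK", ]
  expect_true(rtk2$gene_outlier)
  expect_false(rtk2$both)

  # unmapped group -> set_enriched unknown, with a warning
  expect_warning(
    summ3 <- pathway_outlier_summary(findings, enr, pmap[pmap$pathway_group != "RTK", ]),
    "RTK"
  )
  expect_true(is.na(summ3$set_enriched[summ3$pathway_group == "RTK"]))
})

test_that("spiking several genes of one set flags its group as both", {
  act <- synthetic_actionable_genes()
  pmap <- synthetic_pathway_map(act)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    comp <- simulate_compendium(simulation_config(
      n_genes = 200, n_samples = 80, n_diseases = 2, seed = 500 + r
    ))
    comp$genes$symbol[1:92] <- act$symbol
    rownames(comp$tpm) <- comp$genes$gene_id
    rtk5 <- act$symbol[act$pathway_group == "RTK"][1:5]
    fs <- simulate_focus_sample(
      comp, "disease_01",
      spikes = data.frame(symbol = rtk5, log2_effect = 6), seed = 900 + r
    )
    calls <- call_outliers(fs, comp, outlier_params(), "pan_cancer")
    lists <- combine_outlier_lists(calls, calls)
    findings <- intersect_actionable(lists, act)
    coll <- synthetic_gene_sets(act, extra_genes = comp$genes$symbol[93:200], seed = 1)
    enr <- enrich(lists$pan_cancer, coll, universe = comp$genes$symbol)
    summ <- suppressWarnings(pathway_outlier_summary(findings, enr, pmap))
    if (isTRUE(summ$both[summ$pathway_group == "RTK"])) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
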