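test_that("percentile uses the midrank convention", {
  expect_equal(percentile_of(0, 1:5), 0)
  expect_equal(percentile_of(9, 1:5), 100)
  expect_equal(percentile_of(3, c(1, 2, 3, 4, 5)), 50) # (2 + 0.5)/5 * 100
  expect_equal(percentile_of(7, rep(7, 10)), 50)       # all ties -> midrank
  expect_error(percentile_of(1, numeric(0)), class = "oncoutlier_input_error")
})

test_that("percentile is invariant under joint strictly monotone transforms", {
  set.seed(404)
  for (i in 1:20) {
    cohort <- rnorm(sample(5:50, 1))
    value <- rnorm(1)
    base <- percentile_of(value, cohort)
    expect_equal(percentile_of(exp(value), exp(cohort)), base)
    expect_equal(percentile_of(value^3, cohort^3), base)
    expect_equal(percentile_of(2 * value + 1, 2 * cohort + 1), base)
  }
})

test_that("fence calls match the hand-built examples", {
  # constant cohort: threshold equals the focus value, strict inequality
  comp <- one_gene_compendium(rep(3, 20))
  calls <- call_outliers(one_gene_focus(3), comp,
                         outlier_params(min_cohort_size = 4), "pan_cancer")
  expect_false(calls$is_outlier)
  expect_equal(calls$threshold, 3)
  expect_equal(calls$percentile, 50)

  # cohort log values 1..8: type-7 quartiles 2.75/6.25, fence 11.5;
  # focus 12 sits above both the fence and the floor
  fence <- oracle_fence(1:8)
  expect_equal(fence$threshold, 11.5)
  comp8 <- one_gene_compendium(1:8)
  calls8 <- call_outliers(one_gene_focus(12), comp8,
                          outlier_params(min_cohort_size = 4), "pan_cancer")
  expect_equal(calls8$q1, fence$q1)
  expect_equal(calls8$q3, fence$q3)
  expect_equal(calls8$threshold, fence$threshold)
  expect_true(calls8$is_outlier)
  # just below the fence: not called
  expect_false(
    call_outliers(one_gene_focus(11), comp8,
                  outlier_params(min_cohort_size = 4), "pan_cancer")$is_outlier
  )

  # the expression floor dominates a low absolute value
  low <- call_outliers(one_gene_focus(1), one_gene_compendium(rep(0.1, 20)),
                       outlier_params(min_cohort_size = 4), "pan_cancer")
  expect_gt(low$sample_log, low$threshold)
  expect_false(low$is_outlier)
})

test_that("quartiles and fences match the brute-force oracle", {
  set.seed(99)
  params <- outlier_params(min_cohort_size = 4)
  for (i in 1:50) {
    cohort <- runif(sample(8:40, 1), 0, 8)
    fence <- oracle_fence(cohort)
    calls <- call_outliers(one_gene_focus(4), one_gene_compendium(cohort),
                           params, "pan_cancer")
    expect_equal(calls$q1, fence$q1, tolerance = 1e-9)
    expect_equal(calls$q3, fence$q3, tolerance = 1e-9)
    expect_equal(calls$threshold, fence$threshold, tolerance = 1e-9)
  }
})

test_that("outlier calls are monotone in focus value and fence multiplier", {
  set.seed(7)
  cohort <- runif(30, 0, 6)
  params <- outlier_params(min_cohort_size = 4)
  values <- seq(0, 10, by = 0.25)
  flags <- vapply(values, function(v) {
    call_outliers(one_gene_focus(v), one_gene_compendium(cohort),
                  params, "pan_cancer")$is_outlier
  }, logical(1))
  expect_false(is.unsorted(flags)) # FALSE..FALSE then TRUE..TRUE

  ks <- c(0.5, 1, 1.5, 3, 6)
  n_out <- vapply(ks, function(k) {
    p <- outlier_params(iqr_multiplier = k, min_cohort_size = 4)
    sum(call_outliers(one_gene_focus(5.8), one_gene_compendium(cohort),
                      p, "pan_cancer")$is_outlier)
  }, numeric(1))
  expect_false(is.unsorted(rev(n_out)))
})

test_that("the focus sample is excluded from its own reference cohort", {
  comp <- tiny_compendium(seed = 31, n_samples = 40)
  sid <- comp$metadata$sample_id[1]
  fs <- focus_sample(sid, comp$tpm[, sid], comp)
  calls <- call_outliers(fs, comp, outlier_params(min_cohort_size = 4), "pan_cancer")
  expect_identical(attr(calls, "cohort_size"), ncol(comp$tpm) - 1L)
})

test_that("cohort-size and alignment errors are raised", {
  comp <- one_gene_compendium(1:8)
  expect_error(
    call_outliers(one_gene_focus(2), comp, outlier_params(), "pan_disease"),
    "pan_disease", class = "oncoutlier_input_error"
  )
  fs_bad <- focus_sample("f", c(OTHER = 1))
  expect_error(
    call_outliers(fs_bad, comp, outlier_params(min_cohort_size = 4), "pan_cancer"),
    "cover", class = "oncoutlier_input_error"
  )
})

test_that("a focus identical to a compendium member tops the similarity ranking", {
  comp <- tiny_compendium(seed = 5, n_samples = 40, disease_shift_sd = 1.5)
  target <- comp$metadata$sample_id[7]
  fs <- focus_sample("twin", comp$tpm[, target], comp)
  spec <- select_pan_disease_cohort(fs, comp, k = 20, n_variable_genes = 50)
  expect_identical(spec$similarity$sample_id[1], target)
  expect_equal(spec$similarity$correlation[1], 1)
  expect_true(target %in% spec$member_ids)
})

test_that("k = compendium size returns the whole compendium as cohort", {
  comp <- tiny_compendium(seed = 6, n_samples = 30)
  fs <- simulate_focus_sample(comp, "disease_01", seed = 2)
  spec <- select_pan_disease_cohort(fs, comp, k = 30, n_variable_genes = 40)
  expect_setequal(spec$member_ids, comp$metadata$sample_id)
  sliced <- slice_cohort(comp, spec)
  expect_identical(ncol(sliced$tpm), 30L)
})

test_that("cohort selection rejects invalid k", {
  comp <- tiny_compendium(seed = 6, n_samples = 30)
  fs <- simulate_focus_sample(comp, "disease_01", seed = 2)
  expect_error(select_pan_disease_cohort(fs, comp, k = 5),
               class = "oncoutlier_config_error")
  expect_error(select_pan_disease_cohort(fs, comp, k = 400),
               class = "oncoutlier_config_error")
})

test_that("list combination produces the exact intersection", {
  mk_calls <- function(symbols, outliers, track, sid = "S") {
    tbl <- tibble::tibble(
      gene_id = symbols, symbol = symbols,
      sample_log = 1, q1 = 0, q3 = 0, iqr = 0, threshold = 0, percentile = 50,
      track = track, is_outlier = symbols %in% outliers
    )
    structure(tbl, sample_id = sid,
              class = c("outlier_calls", class(tibble::tibble())))
  }
  pc <- mk_calls(c("A", "B", "C", "D"), c("A", "B", "C"), "pan_cancer")
  pd <- mk_calls(c("A", "B", "C", "D"), c("B", "C", "D"), "pan_disease")
  lists <- combine_outlier_lists(pc, pd)
  expect_identical(lists$pan_cancer, c("A", "B", "C"))
  expect_identical(lists$intersection, c("B", "C"))

  disjoint <- combine_outlier_lists(
    mk_calls(c("A", "B"), "A", "pan_cancer"),
    mk_calls(c("A", "B"), "B", "pan_disease")
  )
  expect_length(disjoint$intersection, 0L)

  same <- combine_outlier_lists(
    mk_calls(c("A", "B"), c("A", "B"), "pan_cancer"),
    mk_calls(c("A", "B"), c("A", "B"), "pan_disease")
  )
  expect_identical(same$intersection, same$pan_cancer)

  expect_error(
    combine_outlier_lists(mk_calls("A", "A", "pan_cancer", sid = "S1"),
                          mk_calls("A", "A", "pan_disease", sid = "S2")),
    "different focus samples"
  )
})
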