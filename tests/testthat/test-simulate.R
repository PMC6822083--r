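test_that("identical config and seed give bit-identical compendia", {
  cfg <- simulation_config(n_genes = 50, n_samples = 40, n_diseases = 2, seed = 3)
  a <- simulate_compendium(cfg)
  b <- simulate_compendium(cfg)
  expect_identical(a$tpm, b$tpm)
  expect_identical(a$metadata, b$metadata)
  c2 <- simulate_compendium(simulation_config(
    n_genes = 50, n_samples = 40, n_diseases = 2, seed = 4
  ))
  expect_false(identical(a$tpm, c2$tpm))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulation_config(n_diseases = 10, n_samples = 5), class = "oncoutlier_config_error")
  expect_error(simulation_config(pediatric_fraction = 1.2), class = "oncoutlier_config_error")
  expect_error(simulation_config(baseline_log_sd = -1), class = "oncoutlier_config_error")
})

test_that("pediatric fraction lands inside its binomial 95% CI", {
  p <- 0.164
  n <- 200
  comp <- simulate_compendium(simulation_config(
    n_genes = 10, n_samples = n, pediatric_fraction = p, seed = 11
  ))
  n_ped <- sum(comp$metadata$age_at_diagnosis < 30)
  half <- 1.96 * sqrt(n * p * (1 - p))
  expect_gte(n_ped, floor(n * p - half))
  expect_lte(n_ped, ceiling(n * p + half))
})

test_that("per-gene log2 means and sds converge to configured values", {
  cfg <- simulation_config(
    n_genes = 100, n_samples = 1000, n_diseases = 2,
    baseline_log_sd = 0.8, disease_shift_sd = 1, seed = 5
  )
  comp <- simulate_compendium(cfg)
  truth <- attr(comp, "truth")
  logm <- log2(comp$tpm + 1)
  ok <- logical(0)
  for (d in colnames(truth$disease_means)) {
    cols <- comp$metadata$sample_id[comp$metadata$disease == d]
    nd <- length(cols)
    # zero-truncation biases genes whose configured mean sits near 0;
    # convergence to the configured value holds where truncation is negligible
    clear <- truth$disease_means[, d] >= 2
    m_hat <- rowMeans(logm[clear, cols])
    s_hat <- apply(logm[clear, cols], 1, sd)
    se_mean <- cfg$baseline_log_sd / sqrt(nd)
    se_sd <- cfg$baseline_log_sd / sqrt(2 * (nd - 1))
    ok <- c(
      ok,
      abs(m_hat - truth$disease_means[clear, d]) <= 3 * se_mean,
      abs(s_hat - cfg$baseline_log_sd) <= 3 * se_sd
    )
  }
  # 3-SE band; a small share of 400 comparisons may graze the boundary
  expect_gte(mean(ok), 0.99)
})

test_that("zero disease shift collapses all diseases onto one distribution", {
  cfg <- simulation_config(
    n_genes = 30, n_samples = 30, n_diseases = 3, disease_shift_sd = 0, seed = 8
  )
  comp <- simulate_compendium(cfg)
  truth <- attr(comp, "truth")
  expect_true(all(truth$disease_means == truth$disease_means[, 1]))
})

test_that("focus samples respect spikes and record ground truth", {
  comp <- tiny_compendium(seed = 21)
  spikes <- data.frame(symbol = c("G0005", "G0010"), log2_effect = c(4, 2))
  fs <- simulate_focus_sample(comp, "disease_02", spikes = spikes, seed = 9)
  expect_s3_class(fs, "focus_sample")
  expect_identical(fs$gene_id, comp$genes$gene_id)
  expect_identical(attr(fs, "truth")$spikes$symbol, spikes$symbol)
  # same seed, no spikes: the spiked genes differ, everything else matches
  fs0 <- simulate_focus_sample(comp, "disease_02", seed = 9)
  spiked <- fs$symbol %in% spikes$symbol
  expect_identical(fs$tpm[!spiked], fs0$tpm[!spiked])
  expect_true(all(fs$tpm[spiked] > fs0$tpm[spiked]))
  expect_error(simulate_focus_sample(comp, "nope", seed = 1), class = "oncoutlier_lookup_error")
  expect_error(
    simulate_focus_sample(comp, "disease_01",
                          spikes = data.frame(symbol = "NOGENE", log2_effect = 1), seed = 1),
    class = "oncoutlier_lookup_error"
  )
})

test_that("a zero-effect spike is indistinguishable from the null draw", {
  comp <- tiny_compendium(seed = 22)
  fs0 <- simulate_focus_sample(comp, "disease_01", seed = 3)
  fsz <- simulate_focus_sample(
    comp, "disease_01",
    spikes = data.frame(symbol = "G0001", log2_effect = 0), seed = 3
  )
  expect_equal(fs0$tpm, fsz$tpm)
})

test_that("dna findings scenarios construct the advertised cells", {
  ids <- sprintf("S%02d", 1:10)
  none <- simulate_dna_findings(ids, "neither", seed = 1)
  expect_identical(nrow(none$dna), 0L)
  expect_identical(nrow(none$rna), 0L)
  expect_true(all(none$truth$venn_cell == "neither"))

  both <- simulate_dna_findings(ids, "both", seed = 1)
  expect_setequal(both$dna$sample_id, ids)
  expect_true(all(both$dna$dna_actionable))
  expect_setequal(both$rna$sample_id, ids)

  expect_error(simulate_dna_findings(ids, "weird", seed = 1))
})

test_that("mixed scenario hits its multinomial cell targets", {
  ids <- sprintf("S%04d", 1:740)
  target <- c(both = 28, dna_only = 6, rna_only = 27, neither = 13) / 74
  mixed <- simulate_dna_findings(ids, "mixed", seed = 17, cell_probs = target)
  frac <- table(factor(mixed$truth$venn_cell, names(target))) / length(ids)
  expect_true(all(abs(as.numeric(frac) - target) <= 0.03))
})
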