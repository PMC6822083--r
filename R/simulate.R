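#' Configuration for the synthetic compendium generator
#'
#' The generator emulates a large, uniformly processed tumor expression
#' compendium: per-gene log2(TPM+1) values are drawn from a normal law whose
#' mean is a shared baseline plus a per-(disease, gene) offset drawn once at
#' compendium creation, then truncated at zero and back-transformed to TPM.
#' Disease offsets are stored with the compendium so focus samples simulated
#' later are exchangeable with compendium members of the same disease.
#'
#' @param n_genes,n_samples,n_diseases Compendium dimensions.
#' @param pediatric_fraction Expected fraction of samples younger than 30
#'   years (default 0.164, a compendium-realistic pediatric/AYA share).
#' @param baseline_log_mean,baseline_log_sd Baseline mean and within-disease
#'   SD of log2(TPM+1) (defaults 3 and 0.8, typical of expressed genes in
#'   uniformly processed tumor compendia).
#' @param disease_shift_sd SD of the per-(disease, gene) mean offsets
#'   (default 1); 0 makes all diseases share one distribution.
#' @param filtered_fraction Fraction of genes flagged as members of the
#'   filtered (pan-cancer) universe (default 0.46, the approximate ratio of
#'   a filtered ~27k-gene set to a full ~58k-gene annotation).
#' @param spike_genes Optional data frame (`symbol`, `log2_effect`) of genes
#'   to spike in focus samples materialized by [write_fixture_workspace()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 500, n_samples = 200, n_diseases = 4,
                              pediatric_fraction = 0.164,
                              baseline_log_mean = 3, baseline_log_sd = 0.8,
                              disease_shift_sd = 1, filtered_fraction = 0.46,
                              spike_genes = NULL, seed = 1L) {
  if (n_genes < 1 || n_samples < 1 || n_diseases < 1) {
    stop_config("n_genes, n_samples and n_diseases must be positive")
  }
  if (n_diseases > n_samples) stop_config("n_diseases cannot exceed n_samples")
  if (pediatric_fraction < 0 || pediatric_fraction > 1) {
    stop_config("pediatric_fraction must lie in [0, 1]")
  }
  if (baseline_log_sd < 0 || disease_shift_sd < 0) {
    stop_config("standard deviations must be >= 0")
  }
  if (filtered_fraction < 0 || filtered_fraction > 1) {
    stop_config("filtered_fraction must lie in [0, 1]")
  }
  if (!is.null(spike_genes)) {
    stopifnot(all(c("symbol", "log2_effect") %in% names(spike_genes)))
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
      n_diseases = as.integer(n_diseases),
      pediatric_fraction = pediatric_fraction,
      baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
      disease_shift_sd = disease_shift_sd, filtered_fraction = filtered_fraction,
      spike_genes = if (is.null(spike_genes)) NULL else as_tibble(spike_genes),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

sim_gene_table <- function(config) {
  i <- seq_len(config$n_genes)
  tibble(
    gene_id = sprintf("SYNG%05d", i),
    symbol = sprintf("G%04d", i),
    in_filtered_universe = i <= round(config$filtered_fraction * config$n_genes)
  )
}

sim_disease_labels <- function(config) sprintf("disease_%02d", seq_len(config$n_diseases))

#' Simulate an expression compendium
#'
#' Draws a gene-by-sample TPM matrix under the model described in
#' [simulation_config()], assigns each sample a disease label (balanced
#' round-robin), and draws ages so the expected under-30 fraction equals
#' `pediatric_fraction` (pediatric ages uniform on \[0, 30), adult ages
#' uniform on \[30, 80)). The per-(disease, gene) mean matrix and the config
#' are stored in the `truth` attribute so downstream tests never re-derive
#' ground truth.
#'
#' @param config A [simulation_config()].
#' @return An [expression_compendium()] with a `truth` attribute.
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- sim_gene_table(config)
  diseases <- sim_disease_labels(config)

  disease_means <- matrix(
    config$baseline_log_mean +
      rnorm(config$n_genes * config$n_diseases, 0, config$disease_shift_sd),
    nrow = config$n_genes, ncol = config$n_diseases,
    dimnames = list(genes$gene_id, diseases)
  )

  sample_disease <- rep_len(diseases, config$n_samples)
  sample_ids <- sprintf("SYNS%05d", seq_len(config$n_samples))
  logm <- matrix(
    rnorm(
      config$n_genes * config$n_samples,
      mean = disease_means[, sample_disease],
      sd = config$baseline_log_sd
    ),
    nrow = config$n_genes,
    dimnames = list(genes$gene_id, sample_ids)
  )
  tpm <- pmax(2^pmax(logm, 0) - 1, 0)

  pediatric <- runif(config$n_samples) < config$pediatric_fraction
  age <- ifelse(pediatric, runif(config$n_samples, 0, 30),
                runif(config$n_samples, 30, 80))
  metadata <- tibble(
    sample_id = sample_ids,
    disease = sample_disease,
    age_at_diagnosis = round(age, 1),
    sex = rep_len(c("female", "male"), config$n_samples),
    site = "synthetic",
    patient_id = paste0("PT", sample_ids)
  )

  comp <- expression_compendium(tpm, genes, metadata)
  attr(comp, "truth") <- list(config = config, disease_means = disease_means)
  comp
}

#' Simulate a focus tumor sample
#'
#' Draws one sample from a given disease's stored compendium distribution,
#' optionally spiking named genes upward by a log2 effect (an engineered
#' overexpressed driver with known ground truth). The spike list is recorded
#' in the sample's `truth` attribute.
#'
#' @param compendium A compendium from [simulate_compendium()].
#' @param disease Disease label present in the compendium.
#' @param spikes `NULL`, or a data frame with `symbol` (or `gene_id`) and
#'   `log2_effect` columns.
#' @param seed Integer seed for this draw.
#' @param sample_id Optional id (default derived from disease and seed).
#' @return A [focus_sample()] tibble with `truth` and `disease` attributes.
#' @export
simulate_focus_sample <- function(compendium, disease, spikes = NULL, seed = 1L,
                                  sample_id = NULL) {
  truth <- attr(compendium, "truth", exact = TRUE)
  if (is.null(truth)) {
    stop_input("compendium lacks simulation ground truth; use simulate_compendium()")
  }
  if (!disease %in% colnames(truth$disease_means)) {
    stop_lookup(paste0("unknown disease '", disease, "'"))
  }
  genes <- compendium$genes
  mu <- truth$disease_means[, disease]
  if (!is.null(spikes)) {
    spikes <- as_tibble(spikes)
    if (!"symbol" %in% names(spikes) && "gene_id" %in% names(spikes)) {
      spikes$symbol <- genes$symbol[match(spikes$gene_id, genes$gene_id)]
    }
    stopifnot(all(c("symbol", "log2_effect") %in% names(spikes)))
    idx <- match(spikes$symbol, genes$symbol)
    if (anyNA(idx)) {
      stop_lookup(paste0("unknown spike gene '", spikes$symbol[which(is.na(idx))[1]], "'"))
    }
    mu[idx] <- mu[idx] + spikes$log2_effect
  }
  set.seed(seed)
  logv <- rnorm(length(mu), mu, truth$config$baseline_log_sd)
  tpm <- pmax(2^pmax(logv, 0) - 1, 0)
  sid <- sample_id %||% sprintf("FOCUS_%s_s%d", disease, as.integer(seed))
  new_focus_sample(
    tibble(gene_id = genes$gene_id, symbol = genes$symbol, tpm = tpm),
    sample_id = sid, disease = disease,
    truth = list(spikes = spikes, disease = disease, seed = as.integer(seed))
  )
}

#' Simulate paired DNA and RNA findings with known concordance
#'
#' Constructs per-sample DNA mutation findings and matching RNA actionable
#' findings so that each sample's expected DNA-vs-RNA Venn cell is known by
#' construction. Scenarios: `both`, `dna_only`, `rna_only`, `neither` assign
#' every sample that cell; `mixed` draws cells independently with
#' `cell_probs`. DNA-positive samples get one actionable mutation in a gene
#' sampled from the actionable table, with its pathway group as the expected
#' downstream group; RNA-positive samples get one actionable outlier
#' finding.
#'
#' @param sample_ids Character vector of sample ids.
#' @param scenario One of `both`, `dna_only`, `rna_only`, `neither`, `mixed`.
#' @param actionable An [actionable_gene_list()] (defaults to the synthetic
#'   92-gene table).
#' @param seed Integer seed.
#' @param cell_probs Named probabilities for the four cells under `mixed`
#'   (default 28:6:27:13 / 74).
#' @return A list with `dna` (findings tibble), `rna` (actionable findings
#'   tibble) and `truth` (tibble `sample_id`, `venn_cell`).
#' @export
simulate_dna_findings <- function(sample_ids,
                                  scenario = c("both", "dna_only", "rna_only", "neither", "mixed"),
                                  actionable = synthetic_actionable_genes(),
                                  seed = 1L,
                                  cell_probs = c(both = 28, dna_only = 6,
                                                 rna_only = 27, neither = 13) / 74) {
  scenario <- rlang::arg_match(scenario)
  actionable <- actionable_gene_list(actionable)
  if (!setequal(names(cell_probs), VENN_CELLS) || any(cell_probs < 0)) {
    stop_config("cell_probs must be nonnegative and named both/dna_only/rna_only/neither")
  }
  set.seed(seed)
  cells <- if (scenario == "mixed") {
    sample(VENN_CELLS, length(sample_ids), replace = TRUE,
           prob = cell_probs[VENN_CELLS])
  } else {
    rep(scenario, length(sample_ids))
  }
  dna_on <- cells %in% c("both", "dna_only")
  rna_on <- cells %in% c("both", "rna_only")

  dna_gene <- sample(actionable$symbol, length(sample_ids), replace = TRUE)
  rna_gene <- sample(actionable$symbol, length(sample_ids), replace = TRUE)

  dna <- tibble(
    sample_id = sample_ids[dna_on],
    gene = dna_gene[dna_on],
    variant = "p.A100V",
    variant_class = "SNV",
    dna_actionable = TRUE,
    rna_mutant_allele_expressed = NA,
    downstream_groups = actionable$pathway_group[match(dna_gene[dna_on], actionable$symbol)]
  )
  rna_idx <- match(rna_gene[rna_on], actionable$symbol)
  rna <- tibble(
    sample_id = sample_ids[rna_on],
    symbol = rna_gene[rna_on],
    class = actionable$class[rna_idx],
    pathway_group = actionable$pathway_group[rna_idx],
    tracks = "pan_cancer",
    drugs = "",
    n_drugs = 0L
  )
  list(dna = dna, rna = rna, truth = tibble(sample_id = sample_ids, venn_cell = cells))
}

#' Synthetic curated tables
#'
#' Stand-ins for the curated inputs the pipeline consumes, built in code so
#' tests and fixtures need no downloads: a 92-gene actionable table (37
#' directly targetable + 55 pathway-targetable genes across nine pathway
#' groups, using real oncology gene symbols), a small offline drug-gene
#' interaction table restricted to the four curated cancer sources, and a
#' pathway-group-to-gene-set mapping matched to [synthetic_gene_sets()].
#' These are synthetic fixtures: the real curated tables can be dropped in
#' as TSV files with the same columns.
#'
#' @return A tibble (or, for [synthetic_gene_sets()], a
#'   [gene_set_collection()]).
#' @export
synthetic_actionable_genes <- function() {
  groups <- list(
    RTK = list(
      direct = c("FLT3", "FGFR1", "FGFR2", "FGFR3", "PDGFRA", "PDGFRB", "KIT",
                 "ALK", "EGFR", "ERBB2", "MET", "RET", "ROS1", "NTRK1"),
      indirect = c("FGFR4", "KDR", "NTRK2", "NTRK3", "ERBB3", "ERBB4", "IGF1R",
                   "CSF1R", "AXL", "DDR2")
    ),
    `PI3K-AKT-mTOR` = list(
      direct = c("PIK3CA", "AKT1", "MTOR"),
      indirect = c("AKT2", "AKT3", "PTEN", "PIK3R1", "RICTOR", "RPTOR", "TSC1", "TSC2")
    ),
    `JAK-STAT` = list(
      direct = c("JAK1", "JAK2", "JAK3"),
      indirect = c("STAT3", "STAT5A", "STAT5B", "IL6", "IL6R", "IL7R")
    ),
    `RAS-RAF-MEK` = list(
      direct = c("BRAF", "MAP2K1", "MAP2K2"),
      indirect = c("KRAS", "NRAS", "HRAS", "RAF1", "MAPK1", "MAPK3", "NF1")
    ),
    SHH = list(
      direct = "SMO",
      indirect = c("PTCH1", "GLI1", "GLI2", "SHH")
    ),
    BCR = list(
      direct = c("BTK", "SYK"),
      indirect = c("LYN", "BLK", "CD79A", "CD79B", "BLNK", "PLCG2")
    ),
    `cell-cycle` = list(
      direct = c("CDK4", "CDK6", "AURKA", "AURKB", "PLK1", "WEE1"),
      indirect = c("CHEK1", "CCND1", "CCND2", "CCND3", "CCNE1", "CDK2", "CDKN2A")
    ),
    HSP = list(
      direct = c("HSP90AA1", "HSP90AB1"),
      indirect = c("HSP90B1", "HSPA5")
    ),
    `BCL2-MDM2` = list(
      direct = c("BCL2", "BCL2L1", "MDM2"),
      indirect = c("MCL1", "MDM4", "TP53", "BIRC5", "XIAP")
    )
  )
  tbl <- purrr::imap_dfr(groups, function(g, name) {
    tibble(
      symbol = c(g$direct, g$indirect),
      class = rep(c("direct", "indirect"), c(length(g$direct), length(g$indirect))),
      pathway_group = name
    )
  })
  actionable_gene_list(tbl)
}

#' @rdname synthetic_actionable_genes
#' @export
synthetic_drug_table <- function() {
  tibble::tribble(
    ~symbol, ~drug, ~source,
    "FLT3", "sorafenib", "CIViC",
    "FLT3", "midostaurin", "My Cancer Genome",
    "BTK", "ibrutinib", "My Cancer Genome",
    "ALK", "crizotinib", "CIViC",
    "EGFR", "erlotinib", "Cancer Commons",
    "CDK4", "palbociclib", "My Cancer Genome",
    "CDK6", "palbociclib", "My Cancer Genome",
    "CDK6", "ribociclib", "My Cancer Genome Clinical Trial",
    "BRAF", "vemurafenib", "CIViC",
    "BRAF", "dabrafenib", "CIViC",
    "SMO", "vismodegib", "My Cancer Genome",
    "JAK2", "ruxolitinib", "CIViC",
    "MDM2", "idasanutlin", "My Cancer Genome Clinical Trial",
    "AURKA", "alisertib", "My Cancer Genome Clinical Trial",
    "MTOR", "everolimus", "Cancer Commons",
    "KIT", "imatinib", "CIViC",
    "PDGFRA", "imatinib", "CIViC",
    "BCL2", "venetoclax", "My Cancer Genome",
    "MAP2K1", "trametinib", "CIViC",
    "HSP90AA1", "onalespib", "My Cancer Genome Clinical Trial"
  )
}

#' @rdname synthetic_actionable_genes
#' @param actionable An [actionable_gene_list()] whose pathway groups the
#'   sets are built from.
#' @param extra_genes Character vector of additional (background) symbols to
#'   mix into each set.
#' @param seed Integer seed used when sampling `extra_genes`.
#' @export
synthetic_gene_sets <- function(actionable = synthetic_actionable_genes(),
                                extra_genes = character(0), seed = 1L) {
  set.seed(seed)
  groups <- split(actionable$symbol, actionable$pathway_group)
  sets <- purrr::imap(groups, function(members, g) {
    pad <- if (length(extra_genes) > 0L) {
      sample(extra_genes, min(length(extra_genes), 5L))
    } else {
      character(0)
    }
    unique(c(members, pad))
  })
  names(sets) <- paste0("SYNTHETIC_", gsub("[^A-Za-z0-9]", "_", toupper(names(sets))), "_SIGNALING")
  gene_set_collection(sets)
}

#' @rdname synthetic_actionable_genes
#' @export
synthetic_pathway_map <- function(actionable = synthetic_actionable_genes()) {
  groups <- sort(unique(actionable$pathway_group))
  tibble(
    pathway_group = groups,
    set_name = paste0("SYNTHETIC_", gsub("[^A-Za-z0-9]", "_", toupper(groups)), "_SIGNALING")
  )
}

#' Materialize a complete synthetic test workspace
#'
#' Writes every file the pipeline reads — expression matrix, gene
#' annotation, sample metadata, focus samples, actionable table, GMT gene
#' sets, drug table, DNA findings, pathway map, disease-group map and a
#' serialized pipeline configuration — into `dir`, and returns the
#' [pipeline_config()] pointing at them. Focus samples are drawn one per
#' disease; genes listed in `config$spike_genes` are spiked into every focus
#' sample. The compendium's actionable-table symbols are embedded into the
#' gene annotation so outlier lists and curated tables share a symbol space.
#'
#' @param dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @param n_focus Number of focus samples (default one per disease).
#' @param dna_scenario Scenario passed to [simulate_dna_findings()] for the
#'   focus samples, or `NULL` to omit DNA data.
#' @param params An [outlier_params()] echoed into the written configuration.
#' @param qc A [qc_rule()]; the default scales the expressed-gene threshold
#'   to half the simulated gene count so synthetic workspaces of any size
#'   pass a meaningful screen.
#' @param cohort_k,n_variable_genes Pan-disease settings for the written
#'   configuration, capped at the workspace dimensions.
#' @return A [pipeline_config()] for the written workspace.
#' @export
write_fixture_workspace <- function(dir, config = simulation_config(),
                                    n_focus = config$n_diseases,
                                    dna_scenario = "mixed",
                                    params = outlier_params(),
                                    qc = qc_rule(min_expressed_genes = floor(config$n_genes / 2)),
                                    cohort_k = max(20L, min(100L, floor(config$n_samples / 2))),
                                    n_variable_genes = min(1000L, config$n_genes)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- simulate_compendium(config)
  actionable <- synthetic_actionable_genes()

  # graft actionable symbols onto the first compendium genes so curated
  # tables and simulated expression share one symbol space
  n_graft <- min(nrow(actionable), nrow(comp$genes))
  comp$genes$symbol[seq_len(n_graft)] <- actionable$symbol[seq_len(n_graft)]
  rownames(comp$tpm) <- comp$genes$gene_id

  p <- function(f) file.path(dir, f)
  write_expression_matrix(comp, p("compendium_tpm.tsv"))
  readr::write_tsv(comp$genes, p("gene_annotation.tsv"))
  readr::write_tsv(comp$metadata, p("sample_metadata.tsv"))
  readr::write_tsv(actionable, p("actionable_genes_synthetic.tsv"))
  readr::write_tsv(synthetic_drug_table(), p("drug_gene_synthetic.tsv"))

  collection <- synthetic_gene_sets(actionable, extra_genes = comp$genes$symbol[-seq_len(n_graft)],
                                    seed = config$seed)
  write_gene_sets(collection, p("gene_sets_synthetic.gmt"))
  readr::write_tsv(synthetic_pathway_map(actionable), p("pathway_map.tsv"))

  diseases <- sim_disease_labels(config)
  disease_groups <- tibble(
    disease = diseases,
    disease_group = rep_len(c("CNS", "HEME", "NBL", "SRC", "other"), length(diseases))
  )
  readr::write_tsv(disease_groups, p("disease_groups.tsv"))

  spikes <- config$spike_genes
  focus <- purrr::map(seq_len(n_focus), function(i) {
    simulate_focus_sample(
      comp, diseases[((i - 1L) %% length(diseases)) + 1L],
      spikes = spikes, seed = child_seed(config$seed, i),
      sample_id = sprintf("FOCUS%03d", i)
    )
  })
  fmat <- do.call(cbind, purrr::map(focus, "tpm"))
  dimnames(fmat) <- list(comp$genes$gene_id, purrr::map_chr(focus, sample_id_of))
  write_expression_matrix(fmat, p("focus_tpm.tsv"))

  if (!is.null(dna_scenario)) {
    findings <- simulate_dna_findings(
      colnames(fmat), dna_scenario, actionable, seed = child_seed(config$seed, 97L)
    )
    readr::write_tsv(findings$dna, p("dna_findings.tsv"))
    readr::write_tsv(findings$truth, p("dna_truth.tsv"))
  }

  cfg <- pipeline_config(
    compendium_matrix = p("compendium_tpm.tsv"),
    gene_annotation = p("gene_annotation.tsv"),
    sample_metadata = p("sample_metadata.tsv"),
    focus_matrix = p("focus_tpm.tsv"),
    actionable_table = p("actionable_genes_synthetic.tsv"),
    gene_sets = p("gene_sets_synthetic.gmt"),
    drug_table = p("drug_gene_synthetic.tsv"),
    dna_findings = if (is.null(dna_scenario)) NULL else p("dna_findings.tsv"),
    pathway_map = p("pathway_map.tsv"),
    disease_groups = p("disease_groups.tsv"),
    params = params, qc = qc,
    cohort_k = cohort_k, n_variable_genes = n_variable_genes,
    out_dir = file.path(dir, "reports"),
    seed = config$seed
  )
  write_pipeline_config(cfg, p("pipeline_config.json"))
  cfg
}
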