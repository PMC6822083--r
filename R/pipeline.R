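#' Declarative pipeline configuration
#'
#' One object holds every path and every science parameter of a run; all
#' effective parameters are echoed into report provenance, so no setting can
#' influence a result silently. The configuration round-trips through JSON
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param compendium_matrix,gene_annotation,sample_metadata,focus_matrix
#'   Paths to the compendium expression matrix, gene annotation, sample
#'   metadata, and focus-sample expression matrix TSVs.
#' @param actionable_table,gene_sets,drug_table,pathway_map Paths to the
#'   curated inputs (actionable TSV, GMT, drug TSV, pathway-group map TSV).
#' @param dna_findings Optional path to the DNA findings TSV; `NULL` when no
#'   DNA data are available (concordance is then marked `not_evaluated`).
#' @param disease_groups Optional path to a disease -> disease-group rollup
#'   TSV used by the recurrence matrix.
#' @param params An [outlier_params()].
#' @param qc An [qc_rule()].
#' @param cohort_k,n_variable_genes Pan-disease cohort size and number of
#'   most-variable genes used for similarity ranking.
#' @param q_cut,max_report Enrichment FDR threshold and report cap.
#' @param out_dir Output directory for written reports.
#' @param seed Integer seed recorded in provenance.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(compendium_matrix, gene_annotation, sample_metadata,
                            focus_matrix, actionable_table, gene_sets,
                            drug_table, pathway_map,
                            dna_findings = NULL, disease_groups = NULL,
                            params = outlier_params(), qc = qc_rule(),
                            cohort_k = 100, n_variable_genes = 1000,
                            q_cut = 0.05, max_report = 100,
                            out_dir = "reports", seed = 1L) {
  structure(
    list(
      paths = list(
        compendium_matrix = compendium_matrix, gene_annotation = gene_annotation,
        sample_metadata = sample_metadata, focus_matrix = focus_matrix,
        actionable_table = actionable_table, gene_sets = gene_sets,
        drug_table = drug_table, pathway_map = pathway_map,
        dna_findings = dna_findings, disease_groups = disease_groups
      ),
      params = params, qc = qc,
      cohort_k = as.integer(cohort_k),
      n_variable_genes = as.integer(n_variable_genes),
      q_cut = as.numeric(q_cut), max_report = as.integer(max_report),
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(
    unclass_deep(config), path,
    auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    compendium_matrix = raw$paths$compendium_matrix,
    gene_annotation = raw$paths$gene_annotation,
    sample_metadata = raw$paths$sample_metadata,
    focus_matrix = raw$paths$focus_matrix,
    actionable_table = raw$paths$actionable_table,
    gene_sets = raw$paths$gene_sets,
    drug_table = raw$paths$drug_table,
    pathway_map = raw$paths$pathway_map,
    dna_findings = raw$paths$dna_findings,
    disease_groups = raw$paths$disease_groups,
    params = outlier_params(
      iqr_multiplier = raw$params$iqr_multiplier,
      min_log_expression = raw$params$min_log_expression,
      min_cohort_size = raw$params$min_cohort_size
    ),
    qc = qc_rule(
      min_expressed_genes = raw$qc$min_expressed_genes,
      min_total_tpm_log_sum = raw$qc$min_total_tpm_log_sum
    ),
    cohort_k = raw$cohort_k, n_variable_genes = raw$n_variable_genes,
    q_cut = raw$q_cut, max_report = raw$max_report,
    out_dir = raw$out_dir, seed = raw$seed
  )
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Load every pipeline input named in a configuration
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_workspace`: list of loaded objects (`compendium`,
#'   `focus` matrix, `actionable`, `gene_sets`, `drug_table`, `pathway_map`,
#'   `dna` findings or `NULL`, `disease_groups` or `NULL`).
#' @export
load_workspace <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pp <- config$paths
  comp <- read_compendium(pp$compendium_matrix, pp$gene_annotation, pp$sample_metadata)
  structure(
    list(
      compendium = comp,
      focus = read_expression_matrix(pp$focus_matrix),
      actionable = read_actionable_table(pp$actionable_table),
      gene_sets = read_gene_sets(pp$gene_sets),
      drug_table = read_drug_table(pp$drug_table),
      pathway_map = read_pathway_map(pp$pathway_map),
      dna = if (is.null(pp$dna_findings)) NULL else read_dna_findings(pp$dna_findings),
      disease_groups = if (is.null(pp$disease_groups)) NULL else {
        readr::read_tsv(pp$disease_groups, show_col_types = FALSE, progress = FALSE)
      },
      config = config
    ),
    class = "pipeline_workspace"
  )
}

workspace_focus_sample <- function(workspace, sample_id) {
  if (!sample_id %in% colnames(workspace$focus)) {
    stop_lookup(paste0("focus sample '", sample_id, "' not in the workspace"))
  }
  focus_sample(sample_id, workspace$focus[, sample_id], workspace$compendium)
}

provenance_of <- function(config) {
  list(
    config_hash = rlang::hash(unclass_deep(config)),
    package_version = as.character(packageVersion("oncoutlier")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = list(
      iqr_multiplier = config$params$iqr_multiplier,
      min_log_expression = config$params$min_log_expression,
      min_cohort_size = config$params$min_cohort_size,
      cohort_k = config$cohort_k,
      n_variable_genes = config$n_variable_genes,
      q_cut = config$q_cut,
      max_report = config$max_report,
      qc_min_expressed_genes = config$qc$min_expressed_genes
    )
  )
}

#' Run the full analysis for one focus sample
#'
#' Executes the per-sample pipeline: QC, gene-universe restriction,
#' pan-cancer outlier calls on the whole compendium (filtered universe),
#' pan-disease cohort selection and outlier calls (full universe), list
#' combination, actionable-gene intersection, drug annotation, enrichment of
#' the three lists, pathway summary, and DNA-vs-RNA concordance when DNA
#' findings are available. A sample failing QC yields a report containing
#' only the QC section.
#'
#' @param workspace A [load_workspace()] result.
#' @param sample A [focus_sample()] tibble, or a sample id present in the
#'   workspace focus matrix.
#' @return A `sample_report`: list with `sample_id`, `qc`, `pan_cancer`,
#'   `pan_disease` (+ `cohort`), `lists`, `findings`, `enrichment` (one
#'   result per list), `pathway_summary`, `concordance` (a record, or the
#'   string `"not_evaluated"` without DNA data), and `provenance`.
#' @export
run_sample <- function(workspace, sample) {
  stopifnot(inherits(workspace, "pipeline_workspace"))
  config <- workspace$config
  if (is.character(sample)) sample <- workspace_focus_sample(workspace, sample)
  check_focus_sample(sample)
  sid <- sample_id_of(sample) %||% "focus"

  qc_tbl <- apply_qc(sample, config$qc)
  report <- list(sample_id = sid, qc = qc_tbl, provenance = provenance_of(config))
  class(report) <- "sample_report"
  if (!qc_tbl$pass[1]) return(report)

  comp <- workspace$compendium
  filtered <- restrict_gene_universe(comp, "filtered")
  pan_cancer <- call_outliers(sample, filtered, config$params, "pan_cancer")

  cohort <- select_pan_disease_cohort(
    sample, comp,
    k = config$cohort_k, n_variable_genes = config$n_variable_genes,
    min_cohort_size = config$params$min_cohort_size
  )
  pan_disease <- call_outliers(
    sample, slice_cohort(comp, cohort), config$params, "pan_disease"
  )

  lists <- combine_outlier_lists(pan_cancer, pan_disease)
  findings <- intersect_actionable(lists, workspace$actionable, sample_id = sid) |>
    annotate_drugs(workspace$drug_table)

  universes <- list(
    pan_cancer = filtered$genes$symbol,
    pan_disease = comp$genes$symbol,
    intersection = filtered$genes$symbol
  )
  enrichment <- purrr::imap(
    list(pan_cancer = lists$pan_cancer, pan_disease = lists$pan_disease,
         intersection = lists$intersection),
    function(genes, nm) {
      enrich(genes, workspace$gene_sets, universe = universes[[nm]],
             q_cut = config$q_cut, max_report = config$max_report,
             list_name = nm)
    }
  )
  pathway_summary <- suppressWarnings(
    pathway_outlier_summary(findings, enrichment, workspace$pathway_map)
  )

  concordance <- if (is.null(workspace$dna)) {
    "not_evaluated"
  } else {
    dna <- workspace$dna |> filter(.data$sample_id == sid)
    classify_sample(
      dna, findings,
      enriched = enriched_groups(pathway_summary),
      outlier_genes = union(lists$pan_cancer, lists$pan_disease),
      sample_id = sid
    )
  }

  report$pan_cancer <- pan_cancer
  report$pan_disease <- pan_disease
  report$cohort <- cohort
  report$lists <- lists
  report$findings <- findings
  report$enrichment <- enrichment
  report$pathway_summary <- pathway_summary
  report$concordance <- concordance
  report
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report>", x$sample_id, "\n")
  if (!x$qc$pass[1]) {
    cat("  failed QC:", x$qc$reason[1], "\n")
    return(invisible(x))
  }
  cat(
    "  outliers: pan-cancer ", length(x$lists$pan_cancer),
    ", pan-disease ", length(x$lists$pan_disease),
    "; actionable findings: ", nrow(x$findings), "\n", sep = ""
  )
  if (is.character(x$concordance)) {
    cat("  concordance: not_evaluated\n")
  } else {
    cat("  concordance:", x$concordance$venn_cell, "/", x$concordance$utility_mode, "\n")
  }
  invisible(x)
}

#' Run the pipeline over a cohort of focus samples
#'
#' Runs [run_sample()] for every focus sample, aggregates concordance
#' records over the subset with DNA data into a [summarize_cohort()] table,
#' computes the RNA-actionability rate over all QC-passing samples, and
#' builds the gene-by-disease-group recurrence matrix of actionable outliers
#' (each cell records the count and whether pan-cancer and/or pan-disease
#' calls contributed).
#'
#' @param workspace A [load_workspace()] result.
#' @param sample_ids Focus sample ids (default: all in the workspace).
#' @return A `cohort_report`: list with `reports` (per sample), `summary`
#'   (concordance summary or `NULL` without DNA data), `actionability`
#'   (per-sample RNA flag tibble), `recurrence` (tibble symbol x
#'   disease_group with `n_samples`, `tracks`), and `provenance`.
#' @export
run_cohort <- function(workspace, sample_ids = NULL) {
  stopifnot(inherits(workspace, "pipeline_workspace"))
  sample_ids <- sample_ids %||% colnames(workspace$focus)
  if (length(sample_ids) < 1L) stop_input("run_cohort needs at least one sample")
  reports <- purrr::map(sample_ids, function(sid) run_sample(workspace, sid))
  names(reports) <- sample_ids

  passing <- purrr::keep(reports, function(r) r$qc$pass[1])
  actionability <- purrr::map_dfr(reports, function(r) {
    tibble(
      sample_id = r$sample_id,
      qc_pass = r$qc$pass[1],
      rna_actionable = if (r$qc$pass[1]) flag_actionable_sample(r$findings) else NA
    )
  })

  records <- purrr::map_dfr(passing, function(r) {
    if (is.data.frame(r$concordance)) r$concordance else tibble()
  })
  summary <- if (nrow(records) > 0L) summarize_cohort(records) else NULL

  disease_groups <- workspace$disease_groups
  recurrence <- purrr::map_dfr(passing, function(r) {
    if (nrow(r$findings) == 0L) return(tibble())
    disease <- attr_disease_of(workspace, r$sample_id)
    r$findings |>
      tidyr::separate_rows("tracks", sep = ";") |>
      mutate(sample_id = r$sample_id, disease = disease) |>
      select("sample_id", "symbol", "disease", track = "tracks")
  })
  if (nrow(recurrence) > 0L) {
    if (!is.null(disease_groups)) {
      recurrence <- recurrence |>
        left_join(disease_groups, by = "disease") |>
        mutate(disease_group = dplyr::coalesce(.data$disease_group, "other"))
    } else {
      recurrence <- mutate(recurrence, disease_group = .data$disease)
    }
    recurrence <- recurrence |>
      summarise(
        n_samples = dplyr::n_distinct(.data$sample_id),
        tracks = join_groups(sort(unique(.data$track))),
        .by = c("symbol", "disease_group")
      ) |>
      arrange(dplyr::desc(.data$n_samples), .data$symbol, .data$disease_group)
  } else {
    recurrence <- tibble(
      symbol = character(0), disease_group = character(0),
      n_samples = integer(0), tracks = character(0)
    )
  }

  structure(
    list(
      reports = reports, summary = summary, actionability = actionability,
      recurrence = recurrence, provenance = provenance_of(workspace$config)
    ),
    class = "cohort_report"
  )
}

attr_disease_of <- function(workspace, sample_id) {
  meta <- workspace$compendium$metadata
  hit <- meta$disease[meta$sample_id == sample_id]
  if (length(hit) == 1L) hit else "unknown"
}

#' @export
print.cohort_report <- function(x, ...) {
  n <- nrow(x$actionability)
  n_rna <- sum(x$actionability$rna_actionable, na.rm = TRUE)
  cat("<cohort_report>", n, "samples;", n_rna, "RNA-actionable\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Write reports to disk
#'
#' Deterministic TSV/JSON writers: two runs with identical inputs, config
#' and seed produce byte-identical files (provenance carries a config hash
#' and versions, never a wall clock).
#'
#' @param report A `sample_report` or `cohort_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory written to.
#' @export
write_sample_report <- function(report, dir) {
  stopifnot(inherits(report, "sample_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, paste0(report$sample_id, "_", f))
  readr::write_tsv(report$qc, p("qc.tsv"))
  jsonlite::write_json(report$provenance, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!report$qc$pass[1]) return(invisible(dir))
  readr::write_tsv(
    bind_rows(as_tibble(report$pan_cancer), as_tibble(report$pan_disease)) |>
      mutate(sample_id = report$sample_id, .before = 1L),
    p("outliers.tsv")
  )
  readr::write_tsv(report$findings, p("findings.tsv"))
  readr::write_tsv(
    purrr::imap_dfr(report$enrichment, function(e, nm) {
      mutate(as_tibble(e), sample_id = report$sample_id, list_name = nm, .before = 1L)
    }),
    p("enrichment.tsv")
  )
  readr::write_tsv(report$pathway_summary, p("pathway_summary.tsv"))
  if (is.data.frame(report$concordance)) {
    readr::write_tsv(report$concordance, p("concordance.tsv"))
  }
  invisible(dir)
}

#' @rdname write_sample_report
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::walk(report$reports, write_sample_report, dir = dir)
  readr::write_tsv(report$actionability, file.path(dir, "cohort_actionability.tsv"))
  readr::write_tsv(report$recurrence, file.path(dir, "cohort_recurrence.tsv"))
  if (!is.null(report$summary)) {
    jsonlite::write_json(
      list(
        n_total = attr(report$summary, "n_total", exact = TRUE),
        metrics = as_tibble(report$summary)
      ),
      file.path(dir, "cohort_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  jsonlite::write_json(report$provenance, file.path(dir, "cohort_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
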