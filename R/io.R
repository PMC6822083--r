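#' Read a TPM expression matrix from TSV
#'
#' Canonical layout is genes-as-rows: a header row of sample ids and a first
#' column of gene ids. The transposed layout is accepted via `orientation`.
#' Ragged rows, duplicate gene ids, missing values and negative values are
#' rejected with an error naming the offending line.
#'
#' @param path Path to a tab-separated file.
#' @param orientation `"genes_in_rows"` (canonical) or `"samples_in_rows"`.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @seealso [write_expression_matrix()], [read_compendium()]
#' @export
read_expression_matrix <- function(path, orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- rlang::arg_match(orientation)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_format(paste0(path, ": empty file"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  bad <- which(lengths(fields) != width)
  if (length(bad) > 0L) {
    stop_format(paste0(path, ": ragged row at line ", bad[1]))
  }
  header <- fields[[1]][-1]
  body <- fields[-1]
  ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(width - 1L))
  )
  mat <- if (width == 2L) matrix(vals, nrow = 1L) else t(vals)
  na_row <- which(apply(is.na(mat), 1L, any))
  if (length(na_row) > 0L) {
    stop_format(paste0(path, ": missing or non-numeric value at line ", na_row[1] + 1L))
  }
  neg_row <- which(apply(mat < 0, 1L, any))
  if (length(neg_row) > 0L) {
    stop_format(paste0(path, ": negative value at line ", neg_row[1] + 1L))
  }
  dimnames(mat) <- list(ids, header)
  if (orientation == "samples_in_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) {
    stop_format(paste0(
      path, ": duplicate gene id '",
      rownames(mat)[duplicated(rownames(mat))][1], "'"
    ))
  }
  mat
}

#' @rdname read_expression_matrix
#' @param x Numeric matrix (genes x samples) or an [expression_compendium()].
#' @export
write_expression_matrix <- function(x, path) {
  if (inherits(x, "expression_compendium")) x <- x$tpm
  tbl <- as_tibble(x, rownames = "gene_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read and write the tabular sidecar files
#'
#' Sample metadata (`sample_id`, `disease`, optional `age_at_diagnosis`,
#' `sex`, `site`, `patient_id`), gene annotation (`gene_id`, `symbol`,
#' `in_filtered_universe`), DNA findings and the pathway-group mapping all
#' travel as plain TSV.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "disease") %in% names(tbl))) {
    stop_format(paste0(path, ": metadata needs sample_id and disease columns"))
  }
  tbl
}

#' @rdname read_sample_metadata
#' @export
read_gene_annotation <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "symbol", "in_filtered_universe")
  if (!all(req %in% names(tbl))) {
    stop_format(paste0(path, ": gene annotation needs ", paste(req, collapse = ", ")))
  }
  tbl$in_filtered_universe <- as.logical(tbl$in_filtered_universe)
  tbl
}

#' @rdname read_sample_metadata
#' @export
read_dna_findings <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "gene", "variant", "variant_class", "dna_actionable")
  if (!all(req %in% names(tbl))) {
    stop_format(paste0(path, ": DNA findings need ", paste(req, collapse = ", ")))
  }
  tbl$dna_actionable <- as.logical(tbl$dna_actionable)
  if (anyNA(tbl$dna_actionable)) {
    stop_format(paste0(path, ": dna_actionable must be defined for every record"))
  }
  if (!"rna_mutant_allele_expressed" %in% names(tbl)) {
    tbl$rna_mutant_allele_expressed <- NA
  }
  tbl$rna_mutant_allele_expressed <- as.logical(tbl$rna_mutant_allele_expressed)
  if (!"downstream_groups" %in% names(tbl)) tbl$downstream_groups <- ""
  tbl$downstream_groups <- dplyr::coalesce(as.character(tbl$downstream_groups), "")
  tbl
}

#' @rdname read_sample_metadata
#' @export
read_pathway_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pathway_group", "set_name") %in% names(tbl))) {
    stop_format(paste0(path, ": pathway map needs pathway_group and set_name columns"))
  }
  tbl
}

#' Read a curated actionable-gene table
#'
#' The table mirrors the structure of a curated 92-gene actionability list:
#' one row per gene symbol, a targetability `class` (`direct` when the protein
#' itself can be inhibited, `indirect` when only its pathway can), and the
#' `pathway_group` the gene signals through. Symbols are uppercased on read;
#' duplicates and unknown classes are rejected.
#'
#' @param path Path to a TSV with columns `symbol`, `class`, `pathway_group`.
#' @return A validated `actionable_gene_list` tibble.
#' @export
read_actionable_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  actionable_gene_list(tbl)
}

#' @rdname read_actionable_table
#' @param entries Data frame with columns `symbol`, `class`, `pathway_group`.
#' @export
actionable_gene_list <- function(entries) {
  tbl <- as_tibble(entries)
  req <- c("symbol", "class", "pathway_group")
  if (!all(req %in% names(tbl))) {
    stop_format(paste0("actionable table needs columns: ", paste(req, collapse = ", ")))
  }
  tbl$symbol <- toupper(tbl$symbol)
  if (anyDuplicated(tbl$symbol)) {
    stop_format(paste0(
      "duplicate actionable symbol '", tbl$symbol[duplicated(tbl$symbol)][1], "'"
    ))
  }
  bad <- setdiff(unique(tbl$class), c("direct", "indirect"))
  if (length(bad) > 0L) {
    stop_format(paste0("unknown actionability class '", bad[1], "'"))
  }
  if (any(is.na(tbl$pathway_group) | !nzchar(tbl$pathway_group))) {
    stop_format("every actionable gene needs a pathway_group")
  }
  class(tbl) <- c("actionable_gene_list", class(tibble()))
  tbl
}

#' Read a local drug-gene interaction table
#'
#' An offline stand-in for a curated drug-gene interaction export restricted
#' to four curated cancer sources. No network queries are ever made; replace
#' the file to use a real export.
#'
#' @param path Path to a TSV with columns `symbol`, `drug`, `source`.
#' @return A tibble; `source` is restricted to CIViC, Cancer Commons,
#'   My Cancer Genome, and My Cancer Genome Clinical Trial.
#' @export
read_drug_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("symbol", "drug", "source")
  if (!all(req %in% names(tbl))) {
    stop_format(paste0(path, ": drug table needs ", paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$source), DRUG_SOURCES)
  if (length(bad) > 0L) {
    stop_format(paste0(path, ": unknown drug source '", bad[1], "'"))
  }
  tbl$symbol <- toupper(tbl$symbol)
  tbl
}

#' Read a gene-set collection from GMT
#'
#' GMT is line-oriented: set name, description, then member genes, all
#' tab-separated. Duplicate set names are rejected; empty sets are dropped
#' with a warning. Member symbols are uppercased.
#'
#' @param path Path to a `.gmt` file.
#' @param universe_size Optional size of the gene universe the sets are drawn
#'   from; defaults to the number of distinct genes across all sets (callers
#'   should normally pass the active analysis universe at enrichment time).
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `universe_size` attribute.
#' @export
read_gene_sets <- function(path, universe_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_set_collection(list(), universe_size = universe_size %||% 0L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short) > 0L) {
    stop_format(paste0(path, ": malformed GMT line ", short[1]))
  }
  nms <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nms
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn(paste0(path, ": dropping ", sum(empty), " empty gene set(s)"))
    sets <- sets[!empty]
  }
  gene_set_collection(sets, universe_size = universe_size)
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors of gene symbols.
#' @export
gene_set_collection <- function(sets, universe_size = NULL) {
  if (length(sets) > 0L && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop_format("every gene set needs a name")
  }
  if (anyDuplicated(names(sets))) {
    stop_format(paste0(
      "duplicate gene set name '", names(sets)[duplicated(names(sets))][1], "'"
    ))
  }
  sets <- lapply(sets, function(s) unique(toupper(s)))
  n_distinct_genes <- length(unique(unlist(sets, use.names = FALSE)))
  universe_size <- universe_size %||% n_distinct_genes
  if (length(sets) > 0L && universe_size < max(lengths(sets))) {
    stop_format("universe_size smaller than the largest gene set")
  }
  structure(sets, universe_size = as.integer(universe_size), class = "gene_set_collection")
}

#' @rdname read_gene_sets
#' @param collection A `gene_set_collection`.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(
    seq_along(collection),
    function(i) paste(c(names(collection)[i], "synthetic", collection[[i]]), collapse = "\t"),
    ""
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(
    "<gene_set_collection> ", length(x), " sets over a universe of ",
    attr(x, "universe_size"), " genes\n", sep = ""
  )
  invisible(x)
}

#' Load a compendium from its three files
#'
#' @param matrix_path Expression matrix TSV (see [read_expression_matrix()]).
#' @param genes_path Gene annotation TSV.
#' @param metadata_path Sample metadata TSV.
#' @inheritParams read_expression_matrix
#' @return An [expression_compendium()].
#' @export
read_compendium <- function(matrix_path, genes_path, metadata_path,
                            orientation = "genes_in_rows") {
  tpm <- read_expression_matrix(matrix_path, orientation)
  genes <- read_gene_annotation(genes_path)
  genes <- genes[match(rownames(tpm), genes$gene_id), , drop = FALSE]
  if (anyNA(genes$gene_id)) {
    stop_format("gene annotation does not cover all matrix genes")
  }
  expression_compendium(tpm, genes, read_sample_metadata(metadata_path))
}

#' Define a sample-level QC rule
#'
#' Library-quality screening applied before any outlier analysis. The default
#' requires at least 10,000 genes with nonzero TPM — a permissive breadth
#' criterion; the rule actually applied is echoed into every report so the
#' screening is reproducible.
#'
#' @param min_expressed_genes Minimum number of genes with TPM > 0.
#' @param min_total_tpm_log_sum Optional floor on the per-sample sum of
#'   log2(TPM+1), a crude total-signal criterion.
#' @return A `qc_rule` object.
#' @export
qc_rule <- function(min_expressed_genes = 10000, min_total_tpm_log_sum = NULL) {
  if (min_expressed_genes < 0) stop_config("min_expressed_genes must be >= 0")
  if (!is.null(min_total_tpm_log_sum) && min_total_tpm_log_sum < 0) {
    stop_config("min_total_tpm_log_sum must be >= 0")
  }
  structure(
    list(
      min_expressed_genes = as.integer(min_expressed_genes),
      min_total_tpm_log_sum = if (is.null(min_total_tpm_log_sum)) NULL else {
        as.numeric(min_total_tpm_log_sum)
      }
    ),
    class = "qc_rule"
  )
}

#' Apply a QC rule to focus samples
#'
#' Partitions samples into passing and failing, with the violated criterion
#' recorded for every failure. The partition is exhaustive and disjoint:
#' every input sample appears exactly once in the result.
#'
#' @param samples A long tibble with columns `sample_id`, `gene_id`, `tpm`, or
#'   a list of [focus_sample()] tibbles.
#' @param rule A [qc_rule()].
#' @return A tibble with one row per sample: `sample_id`,
#'   `n_expressed_genes`, `log_tpm_sum`, `pass`, `reason` (`NA` when passing).
#' @export
apply_qc <- function(samples, rule = qc_rule()) {
  stopifnot(inherits(rule, "qc_rule"))
  if (is.data.frame(samples)) {
    long <- as_tibble(samples)
    if ("sample_id" %in% names(long)) {
      stopifnot(all(c("gene_id", "tpm") %in% names(long)))
    } else {
      check_focus_sample(samples)
      long <- dplyr::mutate(long, sample_id = sample_id_of(samples) %||% "focus")
    }
  } else {
    long <- purrr::map_dfr(samples, function(s) {
      check_focus_sample(s)
      tibble(sample_id = sample_id_of(s), gene_id = s$gene_id, tpm = s$tpm)
    })
  }
  if (nrow(long) == 0L) {
    return(tibble(
      sample_id = character(0), n_expressed_genes = integer(0),
      log_tpm_sum = numeric(0), pass = logical(0), reason = character(0)
    ))
  }
  long |>
    summarise(
      n_expressed_genes = sum(.data$tpm > 0),
      log_tpm_sum = sum(log2_tpm(.data$tpm)),
      .by = "sample_id"
    ) |>
    mutate(
      reason = dplyr::case_when(
        .data$n_expressed_genes < rule$min_expressed_genes ~
          paste0("n_expressed_genes < ", rule$min_expressed_genes),
        !is.null(rule$min_total_tpm_log_sum) &
          .data$log_tpm_sum < (rule$min_total_tpm_log_sum %||% 0) ~
          paste0("log_tpm_sum < ", rule$min_total_tpm_log_sum),
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$reason)
    ) |>
    dplyr::relocate("pass", .before = "reason")
}
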