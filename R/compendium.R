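#' Build an expression compendium
#'
#' The compendium is the reference distribution for every outlier call: a
#' gene-by-sample matrix of TPM values together with a gene annotation table
#' and per-sample clinical metadata. TPM values are stored untransformed; the
#' log2(TPM+1) transform happens at the point of analysis.
#'
#' @param tpm Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` = gene ids and `colnames` = sample ids. All values must be
#'   finite and nonnegative.
#' @param genes Data frame with columns `gene_id`, `symbol`,
#'   `in_filtered_universe` (logical flag marking membership in the filtered
#'   pan-cancer gene universe). Row order must match the matrix rows.
#' @param metadata Data frame with columns `sample_id`, `disease` and
#'   optionally `age_at_diagnosis`, `sex`, `site`, `patient_id`. Every sample
#'   in the matrix must have a metadata row.
#' @return An `expression_compendium` object.
#' @seealso [simulate_compendium()], [read_expression_matrix()],
#'   [restrict_gene_universe()]
#' @export
expression_compendium <- function(tpm, genes, metadata) {
  genes <- as_tibble(genes)
  metadata <- as_tibble(metadata)
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop_format("`tpm` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop_format("`tpm` must carry gene ids as rownames and sample ids as colnames")
  }
  req <- c("gene_id", "symbol", "in_filtered_universe")
  if (!all(req %in% names(genes))) {
    stop_format(paste0("`genes` must have columns: ", paste(req, collapse = ", ")))
  }
  if (!all(c("sample_id", "disease") %in% names(metadata))) {
    stop_format("`metadata` must have columns sample_id and disease")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_format(paste0(
      "duplicate gene ids: ",
      paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")
    ))
  }
  if (nrow(genes) != nrow(tpm) || !identical(genes$gene_id, rownames(tpm))) {
    stop_format("gene annotation does not match matrix rows")
  }
  if (anyNA(tpm)) stop_format("TPM matrix contains missing values")
  if (any(tpm < 0)) stop_format("TPM matrix contains negative values")
  missing_meta <- setdiff(colnames(tpm), metadata$sample_id)
  if (length(missing_meta) > 0L) {
    stop_format(paste0(
      "samples without metadata: ", paste(head(missing_meta, 5L), collapse = ", ")
    ))
  }
  if (any(is.na(metadata$disease) | !nzchar(metadata$disease))) {
    stop_format("every sample needs a nonempty disease label")
  }
  metadata <- metadata[match(colnames(tpm), metadata$sample_id), , drop = FALSE]
  structure(
    list(tpm = tpm, genes = genes, metadata = metadata),
    class = "expression_compendium"
  )
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(
    "<expression_compendium> ", nrow(x$tpm), " genes x ", ncol(x$tpm),
    " samples; ", sum(x$genes$in_filtered_universe),
    " genes in the filtered universe; ",
    dplyr::n_distinct(x$metadata$disease), " diseases\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.expression_compendium <- function(x) dim(x$tpm)

#' Compendium accessors
#'
#' Tidy views of the pieces of an [expression_compendium()]: the gene
#' annotation, the sample metadata, and the expression values in long form.
#'
#' @param compendium An `expression_compendium`.
#' @return A tibble.
#' @export
compendium_genes <- function(compendium) {
  check_compendium(compendium)
  compendium$genes
}

#' @rdname compendium_genes
#' @export
compendium_samples <- function(compendium) {
  check_compendium(compendium)
  compendium$metadata
}

#' @rdname compendium_genes
#' @export
compendium_expression <- function(compendium) {
  check_compendium(compendium)
  as_tibble(compendium$tpm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "tpm")
}

check_compendium <- function(x) {
  if (!inherits(x, "expression_compendium")) {
    stop_input("expected an `expression_compendium` object")
  }
  invisible(x)
}

#' Restrict a compendium to a gene universe
#'
#' Pan-cancer analysis runs on a filtered gene universe (the compendium's
#' analogue of a ~27,000-gene filtered set); pan-disease analysis runs on the
#' full, unfiltered annotation so disease-specific transcripts are not lost.
#' Membership in the filtered universe is an explicit per-gene flag carried in
#' the annotation, never recomputed. Retained genes keep their order.
#'
#' @param compendium An [expression_compendium()].
#' @param universe `"filtered"` keeps only flagged genes; `"unfiltered"`
#'   returns the input unchanged.
#' @return An `expression_compendium` on the requested universe.
#' @export
restrict_gene_universe <- function(compendium, universe = c("filtered", "unfiltered")) {
  check_compendium(compendium)
  universe <- rlang::arg_match(universe)
  if (universe == "unfiltered") return(compendium)
  keep <- compendium$genes$in_filtered_universe
  expression_compendium(
    tpm = compendium$tpm[keep, , drop = FALSE],
    genes = compendium$genes[keep, , drop = FALSE],
    metadata = compendium$metadata
  )
}

#' Build a focus-sample tibble
#'
#' A focus sample is the single tumor profile being compared against the
#' compendium: a long tibble with one row per gene (`gene_id`, `symbol`,
#' `tpm`), carrying the sample id as an attribute so downstream calls can be
#' piped without repeating it.
#'
#' @param sample_id Sample identifier.
#' @param tpm Named numeric vector of TPM values (names = gene ids) or a data
#'   frame with columns `gene_id` and `tpm`.
#' @param compendium Optional [expression_compendium()]; when given, the
#'   vector is aligned (and required to cover) the compendium's gene list and
#'   symbols are attached.
#' @return A `focus_sample` tibble.
#' @export
focus_sample <- function(sample_id, tpm, compendium = NULL) {
  if (is.data.frame(tpm)) {
    stopifnot(all(c("gene_id", "tpm") %in% names(tpm)))
    tbl <- as_tibble(tpm)[, intersect(c("gene_id", "symbol", "tpm"), names(tpm))]
  } else {
    if (is.null(names(tpm))) stop_input("`tpm` vector must be named by gene id")
    tbl <- tibble(gene_id = names(tpm), tpm = as.numeric(tpm))
  }
  if (anyNA(tbl$tpm)) stop_format("focus sample contains missing TPM values")
  if (any(tbl$tpm < 0)) stop_format("focus sample contains negative TPM values")
  if (!is.null(compendium)) {
    check_compendium(compendium)
    missing <- setdiff(compendium$genes$gene_id, tbl$gene_id)
    if (length(missing) > 0L) {
      stop_input(paste0(
        "focus sample is missing ", length(missing),
        " compendium genes (e.g. ", head(missing, 3L)[1], ")"
      ))
    }
    tbl <- tbl[match(compendium$genes$gene_id, tbl$gene_id), , drop = FALSE]
    tbl$symbol <- compendium$genes$symbol
    tbl <- tbl[, c("gene_id", "symbol", "tpm")]
  }
  new_focus_sample(tbl, sample_id = sample_id)
}

new_focus_sample <- function(tbl, sample_id, disease = NULL, truth = NULL) {
  structure(
    as_tibble(tbl),
    sample_id = sample_id,
    disease = disease,
    truth = truth,
    class = c("focus_sample", class(tibble()))
  )
}

#' @rdname focus_sample
#' @param x A `focus_sample`.
#' @export
sample_id_of <- function(x) attr(x, "sample_id", exact = TRUE)

check_focus_sample <- function(x) {
  if (!is.data.frame(x) || !all(c("gene_id", "tpm") %in% names(x))) {
    stop_input("expected a focus sample: a data frame with gene_id and tpm columns")
  }
  invisible(x)
}
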