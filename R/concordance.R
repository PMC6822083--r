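#' Expression support for a DNA finding
#'
#' Grades the RNA evidence behind one mutated gene: `gene_level` when the
#' mutated gene is itself an expression outlier; otherwise `downstream` when
#' any of the pathway groups expected to be active downstream of a functional
#' variant is enriched; otherwise `none`. Absence of a curated downstream
#' mapping means no downstream support can be claimed — conservative by
#' design, mirroring expert review that declines to count pathway links of
#' unknown relevance.
#'
#' @param gene Mutated gene symbol.
#' @param downstream_groups Character vector (or ";"-joined string) of
#'   pathway groups expected active if the variant is functional.
#' @param outlier_genes Character vector of outlier gene symbols for the
#'   sample.
#' @param enriched_groups Character vector of pathway groups whose mapped
#'   gene sets are enriched (see [enriched_groups()]).
#' @return One of `"gene_level"`, `"downstream"`, `"none"`.
#' @export
expression_support_check <- function(gene, downstream_groups, outlier_genes,
                                     enriched_groups) {
  if (length(downstream_groups) == 1L && grepl(";", downstream_groups %||% "")) {
    downstream_groups <- split_groups(downstream_groups)
  }
  if (toupper(gene) %in% toupper(outlier_genes)) return("gene_level")
  downstream_groups <- downstream_groups[!is.na(downstream_groups) & nzchar(downstream_groups)]
  if (length(intersect(downstream_groups, enriched_groups)) > 0L) return("downstream")
  "none"
}

#' Classify one sample's DNA-vs-RNA concordance
#'
#' Joint classification of a sample by its DNA and RNA actionability. The
#' Venn cell is the pair of flags: `dna_flag` is TRUE when any DNA finding
#' is actionable, `rna_flag` when any actionable gene is an expression
#' outlier. The utility mode grades how the RNA evidence modifies the DNA
#' interpretation:
#'
#' * `support` — exactly one actionable DNA gene, and it has expression
#'   support (the gene itself is an outlier, or its downstream pathway
#'   groups are enriched);
#' * `prioritize` — two or more actionable DNA genes, at least one with such
#'   support, so the RNA ranks among them;
#' * `deprioritize` — an actionable DNA finding whose mutant allele is known
#'   not to be expressed and which has no expression support;
#' * `rna_only` — RNA findings with no DNA findings (this mode and the
#'   `rna_only` Venn cell imply each other);
#' * `none` — anything else.
#'
#' An unknown allele-expression status is treated as expressed: a finding is
#' never deprioritized without evidence.
#'
#' @param dna Data frame of DNA findings for one sample (`sample_id`,
#'   `gene`, `variant`, `variant_class`, `dna_actionable`, optional
#'   `rna_mutant_allele_expressed`, `downstream_groups`). May have zero rows.
#' @param rna An `actionable_findings` tibble for the same sample.
#' @param enriched Character vector of enriched pathway groups.
#' @param outlier_genes Character vector of outlier symbols used for the
#'   gene-level support check; defaults to the RNA findings' symbols.
#' @param sample_id Sample id; inferred from the inputs when omitted.
#' @return A one-row `concordance_record` tibble: `sample_id`, `dna_flag`,
#'   `rna_flag`, `venn_cell`, `utility_mode`, `evidence`.
#' @export
classify_sample <- function(dna, rna, enriched = character(0),
                            outlier_genes = NULL, sample_id = NULL) {
  dna <- as_tibble(dna)
  rna <- as_tibble(rna)
  ids <- unique(c(
    if (nrow(dna) > 0L && "sample_id" %in% names(dna)) dna$sample_id,
    if (nrow(rna) > 0L && "sample_id" %in% names(rna)) rna$sample_id
  ))
  if (length(ids) > 1L) {
    stop_input(paste0("conflicting sample ids: ", paste(ids, collapse = ", ")))
  }
  sample_id <- sample_id %||% (if (length(ids) == 1L) ids else "sample")
  outlier_genes <- outlier_genes %||% (if (nrow(rna) > 0L) rna$symbol else character(0))

  if (nrow(dna) > 0L) {
    if (!"rna_mutant_allele_expressed" %in% names(dna)) {
      dna$rna_mutant_allele_expressed <- NA
    }
    if (!"downstream_groups" %in% names(dna)) dna$downstream_groups <- ""
    act <- dna |>
      filter(.data$dna_actionable) |>
      mutate(
        support = purrr::map2_chr(
          .data$gene, .data$downstream_groups,
          function(g, d) expression_support_check(g, d, outlier_genes, enriched)
        )
      )
  } else {
    act <- tibble(gene = character(0), support = character(0),
                  rna_mutant_allele_expressed = logical(0))
  }

  dna_flag <- nrow(act) > 0L
  rna_flag <- nrow(rna) > 0L
  venn_cell <- if (dna_flag && rna_flag) "both" else if (dna_flag) "dna_only" else if (rna_flag) "rna_only" else "neither"

  supported <- act$support != "none"
  unexpressed <- !is.na(act$rna_mutant_allele_expressed) &
    !act$rna_mutant_allele_expressed & !supported
  utility_mode <- if (!dna_flag && rna_flag) {
    "rna_only"
  } else if (dna_flag && nrow(act) == 1L && supported[1]) {
    "support"
  } else if (dna_flag && nrow(act) >= 2L && any(supported)) {
    "prioritize"
  } else if (dna_flag && any(unexpressed)) {
    "deprioritize"
  } else {
    "none"
  }

  evidence <- join_groups(paste0(act$support, ":", act$gene)[supported | unexpressed])
  rec <- tibble(
    sample_id = sample_id,
    dna_flag = dna_flag,
    rna_flag = rna_flag,
    venn_cell = venn_cell,
    utility_mode = utility_mode,
    evidence = evidence
  )
  class(rec) <- c("concordance_record", class(tibble()))
  rec
}

#' Summarize DNA-vs-RNA concordance over a cohort
#'
#' Counts the four Venn cells plus the derived RNA- and DNA-actionable
#' margins, with percentages of the cohort size rounded half-up to one
#' decimal (the conventional clinical-report formatting).
#'
#' @param records A tibble of `concordance_record` rows (one per sample).
#' @return A `cohort_summary` tibble: `metric`, `count`, `percent`, with the
#'   cohort size as attribute `n_total`.
#' @examples
#' records <- tibble::tibble(
#'   venn_cell = rep(c("both", "dna_only", "rna_only", "neither"), c(28, 6, 27, 13))
#' )
#' summarize_cohort(records)
#' @export
summarize_cohort <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) stop_input("cannot summarize an empty cohort")
  bad <- setdiff(unique(records$venn_cell), VENN_CELLS)
  if (length(bad) > 0L) stop_input(paste0("unknown venn cell '", bad[1], "'"))
  n <- nrow(records)
  cell_counts <- vapply(VENN_CELLS, function(cl) sum(records$venn_cell == cl), 0L)
  counts <- c(
    rna_actionable = cell_counts[["both"]] + cell_counts[["rna_only"]],
    dna_actionable = cell_counts[["both"]] + cell_counts[["dna_only"]],
    cell_counts
  )
  out <- tibble(
    metric = names(counts),
    count = as.integer(unname(counts)),
    percent = unname(round_half_up(100 * counts / n, 1))
  )
  structure(out, n_total = n, class = c("cohort_summary", class(tibble())))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", attr(x, "n_total", exact = TRUE), "samples\n")
  NextMethod()
}
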