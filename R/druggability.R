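#' Intersect outlier lists with the actionable-gene table
#'
#' One finding per actionable gene that is an outlier in either track, with
#' the supporting tracks recorded. Matching is exact on uppercased symbols;
#' alias resolution belongs in the data file, not in code.
#'
#' @param lists An `outlier_lists` object from [combine_outlier_lists()].
#' @param actionable An [actionable_gene_list()].
#' @param sample_id Sample id to stamp on findings; defaults to the id
#'   carried by `lists`.
#' @return An `actionable_findings` tibble: `sample_id`, `symbol`, `class`,
#'   `pathway_group`, `tracks` (semicolon-joined subset of
#'   pan_cancer/pan_disease), `drugs` (empty until [annotate_drugs()]).
#' @export
intersect_actionable <- function(lists, actionable, sample_id = NULL) {
  stopifnot(inherits(lists, "outlier_lists"))
  actionable <- actionable_gene_list(actionable)
  sample_id <- sample_id %||% lists$sample_id %||% "focus"

  pc <- toupper(lists$pan_cancer)
  pd <- toupper(lists$pan_disease)
  hits <- actionable |>
    filter(.data$symbol %in% union(pc, pd)) |>
    mutate(
      sample_id = sample_id,
      tracks = purrr::map_chr(.data$symbol, function(s) {
        join_groups(TRACKS[c(s %in% pc, s %in% pd)])
      }),
      drugs = "",
      n_drugs = 0L
    ) |>
    select("sample_id", "symbol", "class", "pathway_group", "tracks", "drugs", "n_drugs") |>
    arrange(.data$symbol)
  class(hits) <- c("actionable_findings", class(tibble()))
  hits
}

#' Attach drug-gene interactions to findings
#'
#' Decorates each finding with every (drug, source) row for its symbol from a
#' local curated table. Findings without any interaction row keep an empty
#' drug list and remain findings: the curated sources do not contain all
#' known drug-gene interactions, so absence of a row is not absence of a
#' drug. Drugs are joined deterministically, ordered by source then drug.
#'
#' @param findings An `actionable_findings` tibble from
#'   [intersect_actionable()].
#' @param drug_table A tibble from [read_drug_table()] (or any data frame
#'   with `symbol`, `drug`, `source`).
#' @return The same findings with `drugs` ("drug\[source\]" joined by ";")
#'   and `n_drugs` filled in.
#' @export
annotate_drugs <- function(findings, drug_table) {
  stopifnot(is.data.frame(findings))
  drug_table <- as_tibble(drug_table)
  stopifnot(all(c("symbol", "drug", "source") %in% names(drug_table)))
  bad <- setdiff(unique(drug_table$source), DRUG_SOURCES)
  if (length(bad) > 0L) stop_format(paste0("unknown drug source '", bad[1], "'"))

  drug_table <- drug_table |>
    mutate(
      symbol = toupper(.data$symbol),
      source = factor(.data$source, levels = DRUG_SOURCES)
    ) |>
    arrange(.data$symbol, .data$source, .data$drug) |>
    mutate(label = paste0(.data$drug, "[", .data$source, "]"))

  joined <- drug_table |>
    summarise(
      drugs = paste(.data$label, collapse = ";"),
      n_drugs = dplyr::n(),
      .by = "symbol"
    )
  out <- findings |>
    select(-dplyr::any_of(c("drugs", "n_drugs"))) |>
    left_join(joined, by = "symbol") |>
    mutate(
      drugs = dplyr::coalesce(.data$drugs, ""),
      n_drugs = dplyr::coalesce(.data$n_drugs, 0L)
    )
  class(out) <- unique(c("actionable_findings", class(out)))
  out
}

#' Is the sample RNA-actionable?
#'
#' TRUE iff at least one actionable gene is an expression outlier in the
#' sample — the per-sample flag behind cohort-level "actionable outlier"
#' percentages.
#'
#' @param findings An `actionable_findings` tibble.
#' @return Logical scalar.
#' @export
flag_actionable_sample <- function(findings) {
  stopifnot(is.data.frame(findings))
  nrow(findings) > 0L
}
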