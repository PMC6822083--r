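#' Hypergeometric upper-tail overlap probability
#'
#' P(X >= overlap) when `list_size` genes are drawn without replacement from
#' a universe of `universe_size` genes of which `set_size` belong to the
#' gene set — the one-sided Fisher enrichment probability that gene-set
#' overlap tools compute.
#'
#' @param overlap Observed overlap between list and set.
#' @param list_size Size of the query gene list.
#' @param set_size Size of the gene set.
#' @param universe_size Size of the gene universe.
#' @return Upper-tail probability in \[0, 1\]. Vectorized over all arguments.
#' @examples
#' hypergeom_overlap_p(2, 3, 4, 10)
#' @export
hypergeom_overlap_p <- function(overlap, list_size, set_size, universe_size) {
  n <- max(length(overlap), length(list_size), length(set_size), length(universe_size))
  overlap <- rep_len(overlap, n)
  list_size <- rep_len(list_size, n)
  set_size <- rep_len(set_size, n)
  universe_size <- rep_len(universe_size, n)
  if (any(overlap < 0 | list_size < 0 | set_size < 0 | universe_size < 0)) {
    stop_input("all margins must be nonnegative")
  }
  if (any(set_size > universe_size | list_size > universe_size)) {
    stop_input("set_size and list_size cannot exceed universe_size")
  }
  if (any(overlap > pmin(set_size, list_size))) {
    stop_input("overlap cannot exceed min(set_size, list_size)")
  }
  if (any(overlap < pmax(0, set_size + list_size - universe_size))) {
    stop_input("overlap below the minimum forced by the margins")
  }
  phyper(overlap - 1, set_size, universe_size - set_size, list_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up FDR adjustment; the result stays aligned with the input order.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return q values in \[0, 1\], same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_input("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-set overlap enrichment of an outlier list
#'
#' Tests every set in the collection for overlap with the query list by the
#' hypergeometric upper tail, adjusts across the whole collection with
#' Benjamini-Hochberg, keeps sets with q below `q_cut`, sorts by
#' (q, p, set name) and reports at most the first `max_report` sets.
#' Query genes outside the universe are dropped (their count is recorded in
#' the `n_dropped` attribute); enrichment p values are universe-sensitive, so
#' the universe size is carried in every result row.
#'
#' @param genes Character vector of gene symbols (an outlier list), or a
#'   data frame with a `symbol` column.
#' @param collection A [gene_set_collection()].
#' @param universe Optional character vector of symbols defining the active
#'   analysis universe (e.g. the filtered universe for a pan-cancer list);
#'   sets and the query are intersected with it. When omitted, the
#'   collection's `universe_size` is used as-is.
#' @param q_cut FDR threshold (default 0.05).
#' @param max_report Number of top sets reported (default 100).
#' @param list_name Optional label recorded on the result.
#' @return An `enrichment_result` tibble: `set_name`, `overlap`, `set_size`,
#'   `list_size`, `universe_size`, `p_value`, `q_value`, `rank`.
#' @export
enrich <- function(genes, collection, universe = NULL, q_cut = 0.05,
                   max_report = 100, list_name = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(genes)) genes <- genes$symbol
  genes <- unique(toupper(genes))

  sets <- unclass(collection)
  attr(sets, "universe_size") <- NULL
  if (!is.null(universe)) {
    universe <- unique(toupper(universe))
    u_size <- length(universe)
    n_dropped <- sum(!genes %in% universe)
    genes <- intersect(genes, universe)
    sets <- lapply(sets, intersect, universe)
  } else {
    u_size <- attr(collection, "universe_size", exact = TRUE)
    n_dropped <- 0L
  }

  empty <- tibble(
    set_name = character(0), overlap = integer(0), set_size = integer(0),
    list_size = integer(0), universe_size = integer(0),
    p_value = numeric(0), q_value = numeric(0), rank = integer(0)
  )
  if (length(sets) == 0L || length(genes) == 0L) {
    return(new_enrichment_result(empty, list_name, n_dropped))
  }

  res <- tibble(
    set_name = names(sets),
    overlap = vapply(sets, function(s) length(intersect(genes, s)), 0L),
    set_size = lengths(sets),
    list_size = length(genes),
    universe_size = u_size
  ) |>
    filter(.data$set_size > 0L) |>
    mutate(
      p_value = hypergeom_overlap_p(
        .data$overlap, .data$list_size, .data$set_size, .data$universe_size
      ),
      q_value = bh_fdr(.data$p_value)
    ) |>
    filter(.data$q_value < q_cut) |>
    arrange(.data$q_value, .data$p_value, .data$set_name) |>
    mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = max_report)
  new_enrichment_result(res, list_name, n_dropped)
}

new_enrichment_result <- function(tbl, list_name, n_dropped) {
  structure(
    as_tibble(tbl),
    list_name = list_name,
    n_dropped = n_dropped,
    class = c("enrichment_result", class(tibble()))
  )
}

#' Per-sample pathway outlier summary
#'
#' Combines gene-level and set-level evidence per pathway group: a group is
#' flagged `gene_outlier` when an actionable gene assigned to it is an
#' expression outlier, and `set_enriched` when any gene set mapped to the
#' group (via the pathway-group mapping table) is significantly enriched.
#' The conjunction of the two flags is the "actionable gene plus its pathway
#' both overexpressed" criterion. Groups with no mapping row get
#' `set_enriched = NA` (unknown) with a warning.
#'
#' @param findings An `actionable_findings` tibble for one sample.
#' @param enrich_results A single `enrichment_result` or a list of them
#'   (e.g. one per outlier list); a set counts as enriched if it appears in
#'   any of them.
#' @param pathway_map Data frame mapping `pathway_group` to `set_name`
#'   (one row per pair).
#' @return A tibble: `sample_id`, `pathway_group`, `gene_outlier`,
#'   `set_enriched`, `both`.
#' @export
pathway_outlier_summary <- function(findings, enrich_results, pathway_map) {
  stopifnot(is.data.frame(findings), is.data.frame(pathway_map))
  stopifnot(all(c("pathway_group", "set_name") %in% names(pathway_map)))
  if (inherits(enrich_results, "enrichment_result")) {
    enrich_results <- list(enrich_results)
  }
  enriched_sets <- unique(unlist(
    purrr::map(enrich_results, "set_name"), use.names = FALSE
  ))
  sid <- if (nrow(findings) > 0L) findings$sample_id[1] else NA_character_

  groups <- sort(unique(c(pathway_map$pathway_group, findings$pathway_group)))
  unmapped <- setdiff(unique(findings$pathway_group), pathway_map$pathway_group)
  if (length(unmapped) > 0L) {
    warn(paste0(
      "pathway group(s) without a set mapping: ", paste(unmapped, collapse = ", ")
    ))
  }
  tibble(
    sample_id = sid,
    pathway_group = groups,
    gene_outlier = groups %in% findings$pathway_group,
    set_enriched = purrr::map_lgl(groups, function(g) {
      mapped <- pathway_map$set_name[pathway_map$pathway_group == g]
      if (length(mapped) == 0L) return(NA)
      any(mapped %in% enriched_sets)
    })
  ) |>
    mutate(both = .data$gene_outlier & .data$set_enriched)
}

#' Pathway groups with enriched sets
#'
#' Convenience accessor: the pathway groups whose mapped sets are enriched,
#' the form the concordance stage consumes.
#'
#' @param summary A tibble from [pathway_outlier_summary()].
#' @return Character vector of pathway groups with `set_enriched = TRUE`.
#' @export
enriched_groups <- function(summary) {
  stopifnot(all(c("pathway_group", "set_enriched") %in% names(summary)))
  summary$pathway_group[!is.na(summary$set_enriched) & summary$set_enriched]
}
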