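#' Plot outlier calls for one sample
#'
#' Expression of the focus sample against the cohort fence: each point is a
#' gene, positioned by its cohort percentile and its log2(TPM+1) value;
#' outliers are highlighted. The dashed line is the expression floor below
#' which no outlier is ever called.
#'
#' @param object An `outlier_calls` tibble from [call_outliers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.outlier_calls <- function(object, ...) {
  params <- attr(object, "params", exact = TRUE)
  ggplot(as_tibble(object), aes(x = .data$percentile, y = .data$sample_log)) +
    geom_point(aes(colour = .data$is_outlier), alpha = 0.6, size = 1) +
    geom_hline(yintercept = params$min_log_expression, linetype = "dashed") +
    scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick"),
      name = "outlier"
    ) +
    labs(
      title = paste0(
        attr(object, "sample_id", exact = TRUE), " — ",
        attr(object, "track", exact = TRUE), " track"
      ),
      x = "percentile in reference cohort",
      y = "log2(TPM + 1)"
    ) +
    theme_minimal()
}

#' Plot an enrichment result
#'
#' Horizontal bars of -log10(q) for the reported gene sets, ordered by rank.
#'
#' @param object An `enrichment_result` from [enrich()].
#' @param top Number of top sets to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, top = 20, ...) {
  tbl <- as_tibble(object) |>
    dplyr::slice_head(n = top) |>
    mutate(set_name = stats::reorder(.data$set_name, -.data$rank))
  ggplot(tbl, aes(x = -log10(.data$q_value), y = .data$set_name)) +
    geom_col(fill = "steelblue") +
    labs(
      title = attr(object, "list_name", exact = TRUE) %||% "gene-set overlap",
      x = expression(-log[10](q)), y = NULL
    ) +
    theme_minimal()
}

#' Plot a cohort concordance summary
#'
#' Bar chart of the four DNA-vs-RNA Venn cells and the two actionability
#' margins, labelled with counts and percentages.
#'
#' @param object A `cohort_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_summary <- function(object, ...) {
  tbl <- as_tibble(object) |>
    mutate(metric = factor(.data$metric, levels = rev(.data$metric)))
  ggplot(tbl, aes(x = .data$percent, y = .data$metric)) +
    geom_col(fill = "darkorange3") +
    geom_text(
      aes(label = paste0(.data$count, " (", .data$percent, "%)")),
      hjust = -0.05, size = 3
    ) +
    xlim(0, 115) +
    labs(
      title = paste0(
        "DNA vs RNA actionability (n = ",
        attr(object, "n_total", exact = TRUE), ")"
      ),
      x = "% of samples", y = NULL
    ) +
    theme_minimal()
}

#' Plot the pan-disease similarity profile
#'
#' Ranked Spearman correlations of compendium samples with the focus sample,
#' colored by disease, with the cohort cutoff marked.
#'
#' @param object A `cohort_spec` from [select_pan_disease_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_spec <- function(object, ...) {
  tbl <- object$similarity |> mutate(rank = dplyr::row_number())
  ggplot(tbl, aes(x = .data$rank, y = .data$correlation, colour = .data$disease)) +
    geom_point(size = 0.8) +
    geom_vline(xintercept = object$k + 0.5, linetype = "dashed") +
    labs(
      title = paste0("most-similar cohort for ", object$focus_sample_id),
      x = "similarity rank", y = "Spearman correlation"
    ) +
    theme_minimal()
}
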