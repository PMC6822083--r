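#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()` returns
#' the per-unit table (per gene, per set, per sample), `glance()` a one-row
#' summary.
#'
#' @param x An `outlier_calls`, `enrichment_result`, `cohort_spec`,
#'   `cohort_summary` or `sample_report` object.
#' @param ... Unused; for generic consistency.
#' @return A tibble.
#' @name oncoutlier-tidiers
NULL

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::tidy
tidy.outlier_calls <- function(x, ...) {
  as_tibble(x) |>
    mutate(sample_id = attr(x, "sample_id", exact = TRUE), .before = 1L)
}

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::glance
glance.outlier_calls <- function(x, ...) {
  params <- attr(x, "params", exact = TRUE)
  tibble(
    sample_id = attr(x, "sample_id", exact = TRUE),
    track = attr(x, "track", exact = TRUE),
    n_genes = nrow(x),
    n_outliers = sum(x$is_outlier),
    cohort_size = attr(x, "cohort_size", exact = TRUE),
    iqr_multiplier = params$iqr_multiplier,
    min_log_expression = params$min_log_expression
  )
}

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  nm <- attr(x, "list_name", exact = TRUE)
  if (!is.null(nm)) out <- mutate(out, list_name = nm, .before = 1L)
  out
}

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble(
    list_name = attr(x, "list_name", exact = TRUE) %||% NA_character_,
    n_significant = nrow(x),
    min_q = if (nrow(x) > 0L) min(x$q_value) else NA_real_,
    n_genes_dropped = attr(x, "n_dropped", exact = TRUE) %||% 0L
  )
}

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::tidy
tidy.cohort_spec <- function(x, ...) x$similarity

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::glance
glance.cohort_spec <- function(x, ...) {
  tibble(
    k = x$k,
    n_variable_genes = x$n_variable_genes,
    top_disease = x$disease_composition$disease[1],
    top_disease_n = x$disease_composition$n[1],
    max_correlation = max(x$similarity$correlation)
  )
}

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) as_tibble(x)

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    as_tibble(x)[, c("metric", "percent")],
    names_from = "metric", values_from = "percent", names_prefix = "pct_"
  )
  mutate(wide, n_total = attr(x, "n_total", exact = TRUE), .before = 1L)
}

#' @rdname oncoutlier-tidiers
#' @exportS3Method generics::glance
glance.sample_report <- function(x, ...) {
  passed <- x$qc$pass[1]
  tibble(
    sample_id = x$sample_id,
    qc_pass = passed,
    n_pan_cancer = if (passed) length(x$lists$pan_cancer) else NA_integer_,
    n_pan_disease = if (passed) length(x$lists$pan_disease) else NA_integer_,
    n_findings = if (passed) nrow(x$findings) else NA_integer_,
    venn_cell = if (passed && is.data.frame(x$concordance)) {
      x$concordance$venn_cell
    } else {
      NA_character_
    }
  )
}
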