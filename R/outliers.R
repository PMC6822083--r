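#' Outlier-analysis parameters
#'
#' The outlier statistic is the classical Tukey upper fence on log2(TPM+1):
#' a gene is called an outlier in the focus tumor when its value exceeds
#' Q3 + `iqr_multiplier` x IQR of the reference cohort *and* clears an
#' absolute expression floor (`min_log_expression`) that suppresses calls
#' among essentially unexpressed genes, where tiny IQRs would otherwise make
#' the fence meaninglessly low. Quartiles use linear interpolation between
#' order statistics (the "type 7" convention) — fixed and documented because
#' quartile conventions move calls near the fence.
#'
#' @param iqr_multiplier Fence multiplier k in Q3 + k x IQR (default 1.5).
#' @param min_log_expression Floor in log2(TPM+1) units (default 2.5).
#' @param min_cohort_size Smallest reference cohort accepted (default 20).
#' @return An `outlier_params` object.
#' @export
outlier_params <- function(iqr_multiplier = 1.5, min_log_expression = 2.5,
                           min_cohort_size = 20) {
  if (iqr_multiplier <= 0) stop_config("iqr_multiplier must be > 0")
  if (min_cohort_size < 4) stop_config("min_cohort_size must be >= 4")
  if (min_log_expression < 0) stop_config("min_log_expression must be >= 0")
  structure(
    list(
      iqr_multiplier = as.numeric(iqr_multiplier),
      min_log_expression = as.numeric(min_log_expression),
      min_cohort_size = as.integer(min_cohort_size)
    ),
    class = "outlier_params"
  )
}

#' Midrank percentile of a value within a cohort
#'
#' The percentile of the focus value among the cohort values, midrank
#' convention: 100 x (number strictly below + half the ties) / cohort size.
#' A value below every cohort member scores 0, above every member 100, and a
#' value equal to all members of a constant cohort scores 50. Invariant under
#' any strictly increasing transform applied jointly to value and cohort.
#'
#' @param value Scalar (e.g. a log2(TPM+1) expression value).
#' @param cohort Nonempty numeric vector on the same scale.
#' @return Percentile in \[0, 100\].
#' @examples
#' percentile_of(3, c(1, 2, 3, 4, 5)) # 50
#' @export
percentile_of <- function(value, cohort) {
  if (length(cohort) == 0L) stop_input("cohort must be nonempty")
  if (anyNA(cohort) || is.na(value)) stop_input("percentile_of does not accept NA")
  100 * (sum(cohort < value) + 0.5 * sum(cohort == value)) / length(cohort)
}

#' Call expression outliers for one focus sample
#'
#' Produces one verdict per gene of the cohort's (already universe-restricted)
#' gene list: cohort quartiles on log2(TPM+1), the Tukey upper fence, the
#' focus sample's midrank percentile in the cohort, and the outlier flag.
#' Only over-expression is called; the fence is one-sided by design because
#' the downstream question is druggable *over*-expression. If the focus
#' sample's id is present in the cohort it is excluded from its own
#' reference distribution.
#'
#' @param sample A [focus_sample()] tibble (or any data frame with `gene_id`
#'   and `tpm` covering the cohort's genes).
#' @param cohort An [expression_compendium()] (the whole compendium for the
#'   pan-cancer track, or a most-similar-samples slice for pan-disease).
#' @param params An [outlier_params()].
#' @param track `"pan_cancer"` or `"pan_disease"`; recorded on every call.
#' @return An `outlier_calls` tibble: `gene_id`, `symbol`, `sample_log`,
#'   `q1`, `q3`, `iqr`, `threshold`, `percentile`, `track`, `is_outlier`,
#'   with the sample id, track, parameters and cohort size as attributes.
#' @seealso [select_pan_disease_cohort()], [combine_outlier_lists()]
#' @export
call_outliers <- function(sample, cohort, params = outlier_params(),
                          track = c("pan_cancer", "pan_disease")) {
  check_focus_sample(sample)
  check_compendium(cohort)
  track <- rlang::arg_match(track)
  stopifnot(inherits(params, "outlier_params"))

  sid <- sample_id_of(sample) %||% "focus"
  keep <- setdiff(colnames(cohort$tpm), sid)
  if (length(keep) < params$min_cohort_size) {
    stop_input(paste0(
      track, " cohort has ", length(keep), " samples; need at least ",
      params$min_cohort_size
    ))
  }
  idx <- match(cohort$genes$gene_id, sample$gene_id)
  if (anyNA(idx)) {
    stop_input("focus sample does not cover all cohort genes")
  }
  s_log <- log2_tpm(sample$tpm[idx])
  logm <- log2_tpm(cohort$tpm[, keep, drop = FALSE])

  qs <- apply(logm, 1L, quantile, probs = c(0.25, 0.75), names = FALSE, type = 7)
  q1 <- unname(qs[1L, ])
  q3 <- unname(qs[2L, ])
  iqr <- q3 - q1
  threshold <- q3 + params$iqr_multiplier * iqr
  s_log <- unname(s_log)
  pct <- unname(
    100 * (rowSums(logm < s_log) + 0.5 * rowSums(logm == s_log)) / length(keep)
  )

  calls <- tibble(
    gene_id = cohort$genes$gene_id,
    symbol = cohort$genes$symbol,
    sample_log = s_log,
    q1 = q1,
    q3 = q3,
    iqr = iqr,
    threshold = threshold,
    percentile = pct,
    track = track,
    is_outlier = s_log > threshold & s_log >= params$min_log_expression
  )
  new_outlier_calls(calls, sample_id = sid, track = track,
                    params = params, cohort_size = length(keep))
}

new_outlier_calls <- function(tbl, sample_id, track, params, cohort_size) {
  structure(
    as_tibble(tbl),
    sample_id = sample_id,
    track = track,
    params = params,
    cohort_size = cohort_size,
    class = c("outlier_calls", class(tibble()))
  )
}

#' Select the most-similar reference cohort (pan-disease track)
#'
#' Ranks every compendium sample by Spearman correlation with the focus
#' sample over the most-variable compendium genes (variance of log2(TPM+1)),
#' and returns the top `k` as the pan-disease reference cohort. Rank-based
#' correlation over variable genes is the standard expression-similarity
#' practice: robust to scale and dominated by genes that actually vary.
#' Ties in correlation are broken by sample id so the cohort is
#' deterministic; the focus sample's own id is never a member.
#'
#' @inheritParams call_outliers
#' @param compendium An [expression_compendium()].
#' @param k Cohort size to return (default 100).
#' @param n_variable_genes Number of most-variable genes the correlation is
#'   computed over (default 1000; capped at the gene count).
#' @param min_cohort_size Smallest admissible `k` (default 20).
#' @return A `cohort_spec`: list with `member_ids`, `similarity` (tibble of
#'   sample id, correlation and disease, sorted nonincreasing), and
#'   `disease_composition` (disease counts among members).
#' @export
select_pan_disease_cohort <- function(sample, compendium, k = 100,
                                      n_variable_genes = 1000,
                                      min_cohort_size = 20) {
  check_focus_sample(sample)
  check_compendium(compendium)
  if (k < min_cohort_size) {
    stop_config(paste0("k = ", k, " is below min_cohort_size = ", min_cohort_size))
  }
  sid <- sample_id_of(sample) %||% "focus"
  keep <- setdiff(colnames(compendium$tpm), sid)
  if (k > length(keep)) {
    stop_config("k exceeds the number of available compendium samples")
  }
  n_variable_genes <- min(n_variable_genes, nrow(compendium$tpm))

  logm <- log2_tpm(compendium$tpm[, keep, drop = FALSE])
  v <- apply(logm, 1L, var)
  top <- order(v, decreasing = TRUE)[seq_len(n_variable_genes)]

  idx <- match(rownames(compendium$tpm), sample$gene_id)
  if (anyNA(idx)) stop_input("focus sample does not cover all compendium genes")
  s_log <- log2_tpm(sample$tpm[idx])

  rho <- as.numeric(cor(logm[top, , drop = FALSE], s_log[top], method = "spearman"))
  meta <- compendium$metadata[match(keep, compendium$metadata$sample_id), ]
  sim <- tibble(sample_id = keep, correlation = rho, disease = meta$disease) |>
    arrange(dplyr::desc(.data$correlation), .data$sample_id)
  members <- sim$sample_id[seq_len(k)]

  structure(
    list(
      member_ids = members,
      similarity = sim,
      disease_composition = sim |>
        dplyr::slice_head(n = k) |>
        dplyr::count(.data$disease, name = "n", sort = TRUE),
      k = k,
      n_variable_genes = n_variable_genes,
      focus_sample_id = sid
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  top_disease <- x$disease_composition$disease[1]
  cat(
    "<cohort_spec> top-", x$k, " most-similar samples (",
    x$n_variable_genes, " variable genes); leading disease: ",
    top_disease, " (", x$disease_composition$n[1], "/", x$k, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Slice a compendium down to a selected cohort
#'
#' @param compendium An [expression_compendium()].
#' @param cohort A `cohort_spec` from [select_pan_disease_cohort()] or a
#'   character vector of sample ids.
#' @return An [expression_compendium()] restricted to the cohort members.
#' @export
slice_cohort <- function(compendium, cohort) {
  check_compendium(compendium)
  ids <- if (inherits(cohort, "cohort_spec")) cohort$member_ids else cohort
  missing <- setdiff(ids, colnames(compendium$tpm))
  if (length(missing) > 0L) {
    stop_lookup(paste0("cohort member not in compendium: ", missing[1]))
  }
  expression_compendium(
    tpm = compendium$tpm[, ids, drop = FALSE],
    genes = compendium$genes,
    metadata = compendium$metadata[match(ids, compendium$metadata$sample_id), ]
  )
}

#' Combine the two outlier tracks into three gene lists
#'
#' The three lists the downstream druggability and enrichment stages consume:
#' the pan-cancer outliers, the pan-disease outliers, and their exact
#' intersection.
#'
#' @param pan_cancer_calls,pan_disease_calls `outlier_calls` tibbles from
#'   [call_outliers()] for the same focus sample.
#' @return An `outlier_lists` object: character vectors `pan_cancer`,
#'   `pan_disease`, `intersection` of outlier gene symbols.
#' @export
combine_outlier_lists <- function(pan_cancer_calls, pan_disease_calls) {
  sid_pc <- attr(pan_cancer_calls, "sample_id", exact = TRUE)
  sid_pd <- attr(pan_disease_calls, "sample_id", exact = TRUE)
  if (!is.null(sid_pc) && !is.null(sid_pd) && !identical(sid_pc, sid_pd)) {
    stop_input("outlier call sets come from different focus samples")
  }
  pc <- sort(unique(pan_cancer_calls$symbol[pan_cancer_calls$is_outlier]))
  pd <- sort(unique(pan_disease_calls$symbol[pan_disease_calls$is_outlier]))
  structure(
    list(
      pan_cancer = pc,
      pan_disease = pd,
      intersection = intersect(pc, pd),
      sample_id = sid_pc %||% sid_pd
    ),
    class = "outlier_lists"
  )
}

#' @export
print.outlier_lists <- function(x, ...) {
  cat(
    "<outlier_lists> pan-cancer: ", length(x$pan_cancer),
    "; pan-disease: ", length(x$pan_disease),
    "; intersection: ", length(x$intersection), "\n", sep = ""
  )
  invisible(x)
}
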