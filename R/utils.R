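#' Round half away from zero
#'
#' Percentage reporting uses the conventional "half-up" rule (37.837 -> 37.8,
#' 68.75 -> 68.8), not the IEC round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(68.75, 37.837, 8.108), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  f <- 10^digits
  # tiny nudge guards against representation error just below .5 boundaries
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

log2_tpm <- function(tpm) log2(tpm + 1)

# single source of truth for the two analysis tracks
TRACKS <- c("pan_cancer", "pan_disease")

DRUG_SOURCES <- c(
  "CIViC", "Cancer Commons", "My Cancer Genome", "My Cancer Genome Clinical Trial"
)

VENN_CELLS <- c("both", "dna_only", "rna_only", "neither")

UTILITY_MODES <- c("support", "prioritize", "deprioritize", "rna_only", "none")

stop_input <- function(msg, class = "oncoutlier_input_error") {
  abort(msg, class = class)
}

stop_format <- function(msg) {
  abort(msg, class = "oncoutlier_format_error")
}

stop_config <- function(msg) {
  abort(msg, class = "oncoutlier_config_error")
}

stop_lookup <- function(msg) {
  abort(msg, class = "oncoutlier_lookup_error")
}

# split "a;b;c" into a character vector, dropping empties
split_groups <- function(x) {
  if (length(x) == 0L || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_groups <- function(x) paste(x, collapse = ";")

# derive a child seed from a master seed; kept below .Machine$integer.max
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}
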