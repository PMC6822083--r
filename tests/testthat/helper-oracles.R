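# Independent oracles, deliberately written from first principles so they
# share no code path with the package implementation.

# linear interpolation between order statistics ("type 7"), by hand
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(xs[n])
  xs[lo + 1] + (h - lo) * (xs[lo + 2] - xs[lo + 1])
}

oracle_fence <- function(x, k = 1.5) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  list(q1 = q1, q3 = q3, threshold = q3 + k * (q3 - q1))
}

# exhaustive enumeration of P(overlap >= k): every size-l draw from a
# universe of u genes of which the first s form the set
oracle_hyper_upper <- function(k, l, s, u) {
  if (l == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(u, l)
  overlaps <- colSums(draws <= s)
  mean(overlaps >= k)
}

# BH step-up written out: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# one-gene compendium wrapper so call_outliers can be checked against the
# quartile oracle on an arbitrary cohort vector (values in log2(TPM+1))
one_gene_compendium <- function(log_values) {
  n <- length(log_values)
  ids <- sprintf("S%03d", seq_len(n))
  tpm <- matrix(2^log_values - 1, nrow = 1,
                dimnames = list("SYNG00001", ids))
  expression_compendium(
    tpm = pmax(tpm, 0),
    genes = tibble::tibble(
      gene_id = "SYNG00001", symbol = "G0001", in_filtered_universe = TRUE
    ),
    metadata = tibble::tibble(sample_id = ids, disease = "d")
  )
}

one_gene_focus <- function(log_value, id = "focus") {
  focus_sample(id, c(SYNG00001 = 2^log_value - 1))
}

tiny_compendium <- function(seed = 42, n_genes = 80, n_samples = 60,
                            n_diseases = 3, ...) {
  simulate_compendium(simulation_config(
    n_genes = n_genes, n_samples = n_samples, n_diseases = n_diseases,
    seed = seed, ...
  ))
}
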