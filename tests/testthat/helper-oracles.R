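# Independent brute-force oracles used against the package implementations.

# Enumerate every (key, sample) pair with naive loops and apply the
# detection + recurrence rules directly.
oracle_blacklist <- function(normal_tables, recurrence_fraction) {
  keys <- unique(unlist(lapply(normal_tables, function(tab)
    variant_key(tab$chrom, tab$pos, tab$ref, tab$alt))))
  hit <- character(0)
  for (k in keys) {
    n_det <- 0L
    for (tab in normal_tables) {
      tab_keys <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
      det <- FALSE
      for (i in seq_len(nrow(tab)))
        if (tab_keys[i] == k && tab$alt_reads[i] >= 3 && tab$vaf[i] > 0.01)
          det <- TRUE
      if (det) n_det <- n_det + 1L
    }
    if (n_det / length(normal_tables) > recurrence_fraction)
      hit <- c(hit, k)
  }
  sort(hit)
}

# Exhaustive two-sided Fisher p-value: enumerate all 2x2 tables with the
# observed margins, point probabilities from binomial coefficients.
oracle_fisher <- function(a, n1, b, n2) {
  k <- a + b
  xs <- max(0, k - n2):min(k, n1)
  prob <- function(x) choose(n1, x) * choose(n2, k - x) / choose(n1 + n2, k)
  p_obs <- prob(a)
  sum(vapply(xs, function(x) {
    p <- prob(x)
    if (p <= p_obs * (1 + 1e-7)) p else 0
  }, numeric(1)))
}
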