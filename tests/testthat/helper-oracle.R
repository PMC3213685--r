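# Independent brute-force enrichment score: materializes the running sum
# literally -- rank genes from highest to lowest expression, walk the list
# incrementing at signature genes (weight / total hit weight) and
# decrementing at the rest (1 / (N - |S|)), return the signed value at the
# maximum absolute deviation from zero (first position wins on ties).
# Kept loop-based and position-by-position so it shares nothing with the
# package's vectorized kernel.
brute_es <- function(expr, sig_genes, weight_mode = "rank",
                     weight_exponent = 1) {
  N <- length(expr)
  o <- order(expr, decreasing = TRUE)
  running <- 0
  best <- 0
  in_sig <- names(expr) %in% sig_genes
  w <- switch(weight_mode,
              rank = N - seq_len(N) + 1,
              expression = unname(abs(expr[o])^weight_exponent),
              unweighted = rep(1, N))
  total_hit_w <- sum(w[in_sig[o]])
  n_miss <- N - sum(in_sig)
  path <- numeric(N)
  for (j in seq_len(N)) {
    g <- o[j]
    if (in_sig[g]) {
      running <- running + w[j] / total_hit_w
    } else {
      running <- running - 1 / n_miss
    }
    path[j] <- running
    # ties in |value| within 1e-12 keep the earlier position
    if (abs(running) > abs(best) + 1e-12) best <- running
  }
  list(es = best, terminal = running, path = path)
}

# random named expression vector over a fixed-size universe
random_profile <- function(n, prefix = "g") {
  stats::setNames(stats::rnorm(n), paste0(prefix, seq_len(n)))
}

# a query of background genes, disjoint from every marker signature
make_query_from_pool <- function(sim, n = 10) {
  sprintf("bg%04d", seq_len(n))
}

# small well-separated simulation used by several suites
small_sim <- function(seed, ...) {
  specr::simulate_mixture(n_subsets = 3, markers_per_subset = 20,
                          n_background_genes = 150, n_samples = 40,
                          marker_fold = 2, noise_sd = 0.5, seed = seed, ...)
}
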