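# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and the library calls behind them).

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1, in input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Hypergeometric upper tail as an explicit sum of binomial-coefficient
# ratios (no distribution functions involved).
hyper_tail_bruteforce <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Full combinatorial enumeration of n-subsets for small N: the fraction of
# subsets containing at least k of the first K elements.
hyper_tail_enumerate <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# One exact-doubling predator series plus exponentially decaying prey,
# sampled at `times`, passing through the stated endpoints.
exact_exponential_pair <- function(times = c(0, 17, 34),
                                   f1 = 378, mu = 0.1575,
                                   b1 = 25e6, b2 = 3.5e6, t_end = 34) {
  g <- log(b1 / b2) / t_end
  list(
    predator = count_series(times, f1 * exp(mu * times),
                            organism = "flagellate"),
    prey = count_series(times, b1 * exp(-g * times), organism = "bacteria"),
    mu = mu, g = g
  )
}

# Small curation fixture: known isoform structure, flags and ORF functions.
make_curation_fixture <- function() {
  df <- data.frame(
    transcript_id = c("t1a", "t1b", "t2a", "t3a", "t3b", "t4a", "t5a"),
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g4", "g5"),
    length = c(300, 500, 400, 250, 250, 600, 350),
    genome_hit = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    transcriptome_hit = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    eukaryote_annotation = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    contaminant = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    orf_functions = c("", "funcA", "funcA;funcB", "funcA;funcA", "",
                      "funcC", ""),
    s1 = c(5, 5, 0, 2, 2, 9, 4),
    s2 = c(3, 3, 1, 0, 0, 8, 4),
    s3 = c(2, 2, 0, 0, 0, 7, 4),
    s4 = c(1, 1, 0, 0, 0, 6, 4),
    stringsAsFactors = FALSE
  )
  transcript_table(df, sample_cols = c("s1", "s2", "s3", "s4"))
}
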