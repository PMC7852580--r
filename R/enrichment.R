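#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes without
#' replacement from a background of `N` genes of which `K` carry the domain,
#' the probability of seeing `k` or more carriers. Evaluated in log space
#' for numerical stability.
#'
#' @param k Observed number of carriers in the subset.
#' @param K Carriers in the background.
#' @param n Subset size.
#' @param N Background size.
#' @return The upper-tail probability in `(0, 1]`; `k = 0` gives exactly 1.
#' @examples
#' hypergeom_tail(4, K = 5, n = 4, N = 10)  # 5/210
#' @export
hypergeom_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf(
      "inconsistent counts: need k <= min(K, n), K <= N, n <= N (got k=%d K=%d n=%d N=%d)",
      k, K, n, N))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Protein-domain enrichment of a gene subset
#'
#' Tests every domain annotated in the background for over-representation in
#' a gene subset (e.g. the genes upregulated in one growth phase), using the
#' hypergeometric upper tail with the whole curated gene set as background
#' and Benjamini-Hochberg control across all tested domains. A gene
#' contributes at most once per domain: repeated annotations of the same
#' domain on one gene collapse to presence/absence.
#'
#' @param subset Character vector of gene identifiers; must be a subset of
#'   `background`.
#' @param background Character vector of background gene identifiers.
#' @param annotations Data frame with `gene_id` and `domain_id` columns;
#'   annotations of genes outside the background are ignored.
#' @param adjusted_p_cutoff BH-adjusted p-value at or below which a domain
#'   is flagged enriched (default 0.05).
#' @return A data frame of class `enrichment_result`, one row per background
#'   domain: `domain_id`, `k` (subset carriers), `n` (subset size), `K`
#'   (background carriers), `N` (background size), `p_value`, `adjusted_p`,
#'   `enrichment_fold_log2` (`log2((k/n) / (K/N))`; `-Inf` when `k = 0`),
#'   `subset_ratio_percent` (`100 * k / n`) and `enriched`. Sorted by
#'   adjusted p then domain.
#' @export
domain_enrichment <- function(subset, background, annotations,
                              adjusted_p_cutoff = 0.05) {
  subset <- unique(as.character(subset))
  background <- unique(as.character(background))
  outside <- setdiff(subset, background)
  if (length(outside) > 0L) {
    stop(sprintf("subset gene(s) absent from the background: %s",
                 paste(utils::head(outside, 5), collapse = ", ")))
  }
  ann <- unique(annotations[annotations$gene_id %in% background,
                            c("gene_id", "domain_id")])
  if (nrow(ann) == 0L) {
    stop("no annotations reference the background genes")
  }
  N <- length(background)
  n <- length(subset)
  domains <- sort(unique(ann$domain_id))
  in_subset <- ann$gene_id %in% subset
  K_tab <- table(factor(ann$domain_id, levels = domains))
  k_tab <- table(factor(ann$domain_id[in_subset], levels = domains))
  K <- as.integer(K_tab)
  k <- as.integer(k_tab)
  p <- vapply(seq_along(domains),
              function(i) hypergeom_tail(k[i], K[i], n, N), numeric(1))
  adj <- bh_adjust(p)
  fold <- ifelse(k == 0, -Inf, log2((k / n) / (K / N)))
  out <- data.frame(domain_id = domains, k = k, n = n, K = K, N = N,
                    p_value = p, adjusted_p = adj,
                    enrichment_fold_log2 = fold,
                    subset_ratio_percent = 100 * k / n,
                    enriched = adj <= adjusted_p_cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$domain_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
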