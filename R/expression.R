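#' Negative-binomial two-sample differential expression test
#'
#' A documented stand-in for pairwise differential testing of a replicated
#' count (or TPM) matrix between two phases. Columns are library-size
#' normalized to a common total; a single common dispersion is estimated
#' across genes by the method of moments (regressing within-group variance
#' excess on the squared mean), and each gene is tested with a
#' negative-binomial score test of equal means:
#' `Z = (mA - mB) / sqrt(V0 * (1/nA + 1/nB))` with `V0 = m0 + phi * m0^2`
#' evaluated at the pooled mean. Fold changes are
#' `log2((mA + pc) / (mB + pc))` with pseudocount `pc` for stability, and
#' p-values are Benjamini-Hochberg adjusted across all tested genes.
#'
#' @param matrix Gene x sample numeric matrix with column names.
#' @param design Data frame with columns `sample_id` and `phase` covering the
#'   matrix columns.
#' @param phase_a,phase_b Phase labels to compare (logFC is A over B).
#' @param dispersion `"estimate"` (common dispersion by method of moments)
#'   or a fixed positive number.
#' @param pseudocount Added to normalized means in the fold change
#'   (default 0.5).
#' @return A data frame of class `de_result` with columns `gene_id`,
#'   `log2_fold_change`, `p_value`, `fdr` and attributes `phase_a`,
#'   `phase_b`, `dispersion`.
#' @seealso [de_classify()] applies decision thresholds; it also accepts
#'   fold-change/FDR tables produced by any other engine.
#' @export
de_test <- function(matrix, design, phase_a, phase_b,
                    dispersion = "estimate", pseudocount = 0.5) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) == 0L) stop("empty expression matrix")
  miss <- setdiff(design$sample_id, colnames(matrix))
  if (length(miss) > 0L) {
    stop(sprintf("design sample(s) missing from the matrix: %s",
                 paste(miss, collapse = ", ")))
  }
  cols_a <- design$sample_id[design$phase == phase_a]
  cols_b <- design$sample_id[design$phase == phase_b]
  n_a <- length(cols_a)
  n_b <- length(cols_b)
  if (n_a < 2L || n_b < 2L) {
    stop("differential testing needs at least 2 replicates per phase")
  }
  sub <- matrix[, c(cols_a, cols_b), drop = FALSE]
  lib <- colSums(sub)
  if (any(lib == 0)) stop("a sample column sums to zero")
  norm <- sweep(sub, 2, lib / mean(lib), "/")
  ya <- norm[, seq_len(n_a), drop = FALSE]
  yb <- norm[, n_a + seq_len(n_b), drop = FALSE]
  ma <- rowMeans(ya)
  mb <- rowMeans(yb)

  if (identical(dispersion, "estimate")) {
    # pooled within-group variance; E[s2] = mu + phi mu^2 under NB, so
    # regress the variance excess on mu^2 through the origin
    va <- apply(ya, 1, stats::var)
    vb <- apply(yb, 1, stats::var)
    s2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
    m0 <- (n_a * ma + n_b * mb) / (n_a + n_b)
    phi <- sum(m0^2 * (s2 - m0)) / sum(m0^4)
    phi <- max(phi, 1e-8)
  } else {
    if (!is.numeric(dispersion) || dispersion <= 0) {
      stop("'dispersion' must be \"estimate\" or a positive number")
    }
    phi <- dispersion
  }

  m0 <- (n_a * ma + n_b * mb) / (n_a + n_b)
  v0 <- m0 + phi * m0^2
  se <- sqrt(v0 * (1 / n_a + 1 / n_b))
  z <- ifelse(se > 0, (ma - mb) / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))

  out <- data.frame(gene_id = rownames(sub) %||% sprintf("gene%d",
                                                         seq_len(nrow(sub))),
                    log2_fold_change = lfc,
                    p_value = p,
                    fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "phase_a") <- phase_a
  attr(out, "phase_b") <- phase_b
  attr(out, "dispersion") <- phi
  class(out) <- c("de_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement,
#' preserving input order. Inputs outside `[0, 1]` are rejected.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify differential expression at fixed thresholds
#'
#' A gene is called differentially expressed iff `|logFC| > logfc_threshold`
#' and `fdr < fdr_threshold`, both strict, with the direction given by the
#' sign of the fold change. Besides `de_result` objects this accepts any
#' data frame with `log2_fold_change` and `fdr` columns, so thresholds and
#' downstream accounting can be applied to the output of any DE engine.
#'
#' @param results A [de_test()] result or a compatible data frame.
#' @param logfc_threshold Absolute log2 fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold (default 1e-3).
#' @return The input data frame with a `direction` column (`"up_a"`,
#'   `"up_b"`, `"not_de"`) plus attribute `counts` (named vector with
#'   `up_a`, `up_b`, `total_de`).
#' @export
de_classify <- function(results, logfc_threshold = 2, fdr_threshold = 1e-3) {
  need <- c("log2_fold_change", "fdr")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0L) {
    stop(sprintf("results are missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  de <- abs(results$log2_fold_change) > logfc_threshold &
    results$fdr < fdr_threshold
  direction <- ifelse(!de, "not_de",
                      ifelse(results$log2_fold_change > 0, "up_a", "up_b"))
  results$direction <- direction
  counts <- c(up_a = sum(direction == "up_a"),
              up_b = sum(direction == "up_b"),
              total_de = sum(de))
  attr(results, "counts") <- counts
  results
}

#' Per-phase mean expression
#'
#' Arithmetic mean of expression values across the samples of each phase;
#' biological and technical replicates are pooled.
#'
#' @param matrix Gene x sample numeric matrix with column names.
#' @param design Data frame with `sample_id` and `phase` covering all matrix
#'   columns.
#' @return Gene x phase matrix of means (phases in design order).
#' @export
phase_mean <- function(matrix, design) {
  matrix <- as.matrix(matrix)
  miss <- setdiff(colnames(matrix), design$sample_id)
  if (length(miss) > 0L) {
    stop(sprintf("sample(s) without a phase assignment: %s",
                 paste(miss, collapse = ", ")))
  }
  phases <- unique(design$phase)
  out <- vapply(phases, function(ph) {
    cols <- design$sample_id[design$phase == ph]
    cols <- intersect(cols, colnames(matrix))
    if (length(cols) == 0L) {
      stop(sprintf("phase '%s' has no samples in the matrix", ph))
    }
    rowMeans(matrix[, cols, drop = FALSE])
  }, numeric(nrow(matrix)))
  out <- base::matrix(out, nrow = nrow(matrix),
                      dimnames = list(rownames(matrix), phases))
  out
}

#' Select highly expressed genes
#'
#' A gene qualifies when its mean TPM strictly exceeds `threshold` in at
#' least one phase.
#'
#' @param phase_means Gene x phase matrix from [phase_mean()].
#' @param threshold TPM threshold (default 500, strict).
#' @return Character vector of selected gene identifiers.
#' @export
highly_expressed_select <- function(phase_means, threshold = 500) {
  phase_means <- as.matrix(phase_means)
  sel <- apply(phase_means, 1, max) > threshold
  rownames(phase_means)[sel]
}

#' Partition highly expressed genes by differential direction
#'
#' Splits a highly-expressed gene set into three disjoint, exhaustive
#' classes using classified pairwise results between two phases (typically
#' exponential vs stationary): up in the first phase, up in the second, and
#' similarly expressed.
#'
#' @param heg_set Character vector of gene identifiers; every gene must be
#'   present in `classified`.
#' @param classified Output of [de_classify()] (needs `gene_id` and
#'   `direction` columns).
#' @return A list with `up_a`, `up_b`, `similar` character vectors and a
#'   `sizes` integer vector.
#' @export
partition_heg <- function(heg_set, classified) {
  miss <- setdiff(heg_set, classified$gene_id)
  if (length(miss) > 0L) {
    stop(sprintf("gene(s) missing from the DE results: %s",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  dirs <- classified$direction[match(heg_set, classified$gene_id)]
  out <- list(up_a = heg_set[dirs == "up_a"],
              up_b = heg_set[dirs == "up_b"],
              similar = heg_set[dirs == "not_de"])
  out$sizes <- c(up_a = length(out$up_a), up_b = length(out$up_b),
                 similar = length(out$similar))
  out
}

#' Aggregate phase-mean expression by functional category
#'
#' Adds up the phase-mean TPM of the member genes of each functional
#' category, then expresses each row as a percentage of its own maximum
#' (the highest phase = 100%), reporting that maximum TPM alongside —
#' the summary behind category-by-phase expression heatmaps.
#'
#' @param phase_means Gene x phase matrix from [phase_mean()].
#' @param category_map Data frame with `gene_id` and a category column.
#' @param level Name of the category column to aggregate on (default
#'   `"cellular_function"`).
#' @return A data frame: `category`, `n_genes`, one `tpm_<phase>` and one
#'   `pct_<phase>` column per phase, and `max_tpm`. Every row's maximum
#'   percentage is exactly 100. Genes without a category entry must not be
#'   present; categories with no genes in the matrix are omitted with a
#'   warning.
#' @export
functional_aggregate <- function(phase_means, category_map,
                                 level = "cellular_function") {
  phase_means <- as.matrix(phase_means)
  if (!level %in% names(category_map)) {
    stop(sprintf("category map has no '%s' column", level))
  }
  uncat <- setdiff(rownames(phase_means), category_map$gene_id)
  if (length(uncat) > 0L) {
    stop(sprintf("gene(s) without a category: %s",
                 paste(utils::head(uncat, 5), collapse = ", ")))
  }
  cats <- unique(category_map[[level]])
  rows <- lapply(cats, function(cc) {
    genes <- category_map$gene_id[category_map[[level]] == cc]
    genes <- intersect(genes, rownames(phase_means))
    if (length(genes) == 0L) {
      warning(sprintf("category '%s' has no genes in the matrix; omitted", cc))
      return(NULL)
    }
    sums <- colSums(phase_means[genes, , drop = FALSE])
    mx <- max(sums)
    pct <- if (mx == 0) rep(0, length(sums)) else 100 * sums / mx
    row <- data.frame(category = cc, n_genes = length(genes),
                      stringsAsFactors = FALSE)
    for (ph in colnames(phase_means)) {
      row[[paste0("tpm_", ph)]] <- sums[[ph]]
    }
    for (ph in colnames(phase_means)) {
      row[[paste0("pct_", ph)]] <- pct[[ph]]
    }
    row$max_tpm <- mx
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation between samples
#'
#' Correlation of expression profiles between every pair of samples,
#' typically restricted to differentially expressed genes. Samples with zero
#' variance have undefined correlations, reported as `NA` (never coerced
#' to 0).
#'
#' @param matrix Gene x sample numeric matrix with at least 2 genes.
#' @return Symmetric sample x sample correlation matrix with unit diagonal
#'   for well-defined samples.
#' @export
sample_correlation <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) {
    stop("sample correlation needs at least 2 genes")
  }
  suppressWarnings(r <- stats::cor(matrix))
  degenerate <- apply(matrix, 2, stats::sd) == 0
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r)[!degenerate] <- 1
  r
}
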