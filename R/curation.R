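#' Construct a transcript table
#'
#' The working container for transcriptome curation: one row per transcript
#' with its gene, length, per-sample counts, evidence flags, and any
#' predicted ORF functions. Counts live in ordinary numeric columns named in
#' `sample_cols`; ORF functions are stored as a single `;`-separated string
#' (empty string when no ORF was predicted) so that the table round-trips
#' through TSV.
#'
#' @param df A data frame with at least `transcript_id`, `gene_id`, `length`
#'   plus logical columns `genome_hit`, `transcriptome_hit`,
#'   `eukaryote_annotation`, `contaminant` and character `orf_functions`.
#'   Missing flag columns default to `FALSE` and missing `orf_functions` to
#'   `""`.
#' @param sample_cols Character vector naming the per-sample count columns.
#' @return A `transcript_table` (data frame subclass with a `sample_cols`
#'   attribute).
#' @export
transcript_table <- function(df, sample_cols = character()) {
  need <- c("transcript_id", "gene_id", "length")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("transcript table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  for (fl in c("genome_hit", "transcriptome_hit", "eukaryote_annotation",
               "contaminant")) {
    if (is.null(df[[fl]])) df[[fl]] <- FALSE
    df[[fl]] <- as.logical(df[[fl]])
  }
  if (is.null(df$orf_functions)) df$orf_functions <- ""
  df$orf_functions[is.na(df$orf_functions)] <- ""
  if (anyDuplicated(df$transcript_id)) {
    stop("'transcript_id' must be unique within a transcript table")
  }
  if (any(df$length <= 0)) stop("transcript lengths must be positive")
  miss_s <- setdiff(sample_cols, names(df))
  if (length(miss_s) > 0L) {
    stop(sprintf("sample column(s) not found: %s",
                 paste(miss_s, collapse = ", ")))
  }
  for (s in sample_cols) {
    if (any(df[[s]] < 0)) stop(sprintf("negative counts in sample '%s'", s))
  }
  attr(df, "sample_cols") <- as.character(sample_cols)
  class(df) <- c("transcript_table", "data.frame")
  df
}

#' @export
print.transcript_table <- function(x, ...) {
  cat(sprintf("<transcript_table> %d transcripts, %d genes, %d samples\n",
              nrow(x), length(unique(x$gene_id)),
              length(attr(x, "sample_cols"))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# rebuild the subclass after row filtering
retable <- function(df, template) {
  attr(df, "sample_cols") <- attr(template, "sample_cols")
  class(df) <- c("transcript_table", "data.frame")
  rownames(df) <- NULL
  df
}

#' Keep the longest isoform of each gene
#'
#' Collapses an assembled isoform table to one representative transcript per
#' gene: the longest isoform, with length ties broken toward the
#' lexicographically smallest transcript identifier for determinism.
#'
#' @param table A [transcript_table()].
#' @return A `transcript_table` with one row per `gene_id`.
#' @export
longest_isoform <- function(table) {
  stopifnot(inherits(table, "transcript_table"))
  if (nrow(table) == 0L) return(table)
  ord <- order(table$gene_id, -table$length, table$transcript_id)
  sorted <- as.data.frame(table)[ord, , drop = FALSE]
  keep <- !duplicated(sorted$gene_id)
  out <- sorted[keep, , drop = FALSE]
  retable(out[order(out$transcript_id), , drop = FALSE], table)
}

#' Filter transcripts by taxonomic evidence
#'
#' First pass keeps transcripts with any positive evidence of belonging to
#' the target eukaryote: a match to its genome, a match to a reference
#' transcriptome, or a eukaryotic taxonomic annotation. A second pass then
#' removes transcripts flagged as contaminants (obvious bacterial or viral
#' genes), even when they carried positive evidence.
#'
#' @param table A [transcript_table()].
#' @return Filtered `transcript_table`.
#' @export
evidence_filter <- function(table) {
  stopifnot(inherits(table, "transcript_table"))
  kept <- table$genome_hit | table$transcriptome_hit |
    table$eukaryote_annotation
  out <- as.data.frame(table)[kept, , drop = FALSE]
  out <- out[!out$contaminant, , drop = FALSE]
  retable(out, table)
}

#' Filter transcripts by sample prevalence
#'
#' A transcript "appears" in a sample when its count reaches
#' `detection_threshold`; transcripts appearing in fewer than `min_samples`
#' samples are dropped. The fraction of total signal (summed counts) carried
#' by the dropped transcripts is reported alongside.
#'
#' @param table A [transcript_table()] with sample columns.
#' @param min_samples Minimum number of samples a transcript must appear in
#'   (default 3).
#' @param detection_threshold Count at or above which a transcript counts as
#'   present in a sample (default 1).
#' @return A list with `table` (filtered) and `removed_signal_fraction`.
#' @export
prevalence_filter <- function(table, min_samples = 3,
                              detection_threshold = 1) {
  stopifnot(inherits(table, "transcript_table"))
  samples <- attr(table, "sample_cols")
  if (min_samples > length(samples)) {
    stop(sprintf("'min_samples' = %d exceeds the %d available samples",
                 min_samples, length(samples)))
  }
  counts <- as.matrix(as.data.frame(table)[, samples, drop = FALSE])
  appearances <- rowSums(counts >= detection_threshold)
  keep <- appearances >= min_samples
  total <- sum(counts)
  removed <- if (total == 0) 0 else sum(counts[!keep, , drop = FALSE]) / total
  list(table = retable(as.data.frame(table)[keep, , drop = FALSE], table),
       removed_signal_fraction = removed)
}

#' Split chimeric multi-ORF transcripts
#'
#' A transcript carrying two or more predicted ORFs is split into one record
#' per ORF when the predicted functions are not all identical (the signature
#' of a chimeric assembly joining distinct genes). Split parts get suffixed
#' identifiers (`<id>_p1`, `<id>_p2`, ...) and inherit the parent's
#' per-sample counts and length; transcripts with zero or one ORF, or with
#' several ORFs of one shared function, pass through unchanged.
#'
#' @param table A [transcript_table()].
#' @return A `transcript_table`, possibly with more rows than the input.
#' @export
split_multi_orf <- function(table) {
  stopifnot(inherits(table, "transcript_table"))
  if (nrow(table) == 0L) return(table)
  df <- as.data.frame(table)
  orfs <- strsplit(df$orf_functions, ";", fixed = TRUE)
  n_orf <- lengths(orfs)
  distinct <- vapply(orfs, function(x) length(unique(x)), integer(1))
  to_split <- n_orf >= 2L & distinct > 1L
  if (!any(to_split)) return(table)
  pieces <- lapply(seq_len(nrow(df)), function(i) {
    if (!to_split[i]) return(df[i, , drop = FALSE])
    parts <- df[rep(i, n_orf[i]), , drop = FALSE]
    parts$transcript_id <- sprintf("%s_p%d", df$transcript_id[i],
                                   seq_len(n_orf[i]))
    parts$gene_id <- sprintf("%s_p%d", df$gene_id[i], seq_len(n_orf[i]))
    parts$orf_functions <- orfs[[i]]
    parts
  })
  retable(do.call(rbind, pieces), table)
}

#' Gene count implied by a transcript-splitting histogram
#'
#' Given a base number of transcripts and a histogram of how many were split
#' into how many parts, returns the resulting gene count:
#' `n_base + sum(count * (parts - 1))`. Splitting a transcript into `p`
#' parts replaces one record with `p`, adding `p - 1`.
#'
#' @param n_base Number of transcripts before splitting.
#' @param split_histogram Named list or vector mapping number of parts
#'   (>= 2) to the number of transcripts split into that many parts. May be
#'   empty.
#' @return Integer gene count after splitting.
#' @examples
#' split_accounting(15123, c("2" = 866, "3" = 92, "4" = 12))  # 16209
#' @export
split_accounting <- function(n_base, split_histogram = c()) {
  if (length(split_histogram) == 0L) return(as.integer(n_base))
  parts <- as.integer(names(split_histogram))
  if (anyNA(parts) || any(parts < 2L)) {
    stop("split histogram keys must be integer part counts >= 2")
  }
  counts <- as.integer(unlist(split_histogram, use.names = FALSE))
  if (any(counts < 0L)) stop("split histogram counts must be non-negative")
  as.integer(n_base + sum(counts * (parts - 1L)))
}

#' Transcripts-per-million normalization
#'
#' Per sample: `rate_i = count_i / length_i`, then
#' `TPM_i = 1e6 * rate_i / sum(rate)`. Every non-degenerate sample column
#' sums to exactly one million; an all-zero sample yields an all-zero TPM
#' column and is flagged in the `zero_samples` attribute.
#'
#' @param counts Gene x sample numeric matrix (non-negative).
#' @param lengths Transcript lengths in bases, one per gene, all positive.
#' @return Gene x sample TPM matrix with attribute `zero_samples`.
#' @examples
#' compute_tpm(cbind(s1 = c(10, 90)), c(1000, 3000))  # 250000 / 750000
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) {
    stop("'lengths' must have one entry per gene (row)")
  }
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  totals <- colSums(rate)
  zero <- totals == 0
  totals[zero] <- 1  # avoid 0/0; those columns are all zero anyway
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  attr(tpm, "zero_samples") <- colnames(counts)[zero]
  tpm
}

#' Run the full transcriptome curation chain with accounting
#'
#' Applies, in order: longest-isoform selection, evidence filtering (with
#' contaminant removal), prevalence filtering, and multi-ORF splitting, and
#' records the table size after every stage in a `curation_report`.
#'
#' @param table A [transcript_table()].
#' @param min_samples,detection_threshold Passed to [prevalence_filter()].
#' @return A list with `table` (curated) and `report` (a `curation_report`:
#'   counts `n_input`, `n_after_isoform`, `n_after_evidence`,
#'   `n_after_prevalence`, `n_after_contaminant`, `n_after_split` and
#'   `removed_signal_fraction`).
#' @export
curate_transcripts <- function(table, min_samples = 3,
                               detection_threshold = 1) {
  stopifnot(inherits(table, "transcript_table"))
  n_input <- nrow(table)
  t1 <- longest_isoform(table)
  # evidence pass split in two so the report can count both stages
  kept <- t1$genome_hit | t1$transcriptome_hit | t1$eukaryote_annotation
  t2 <- retable(as.data.frame(t1)[kept, , drop = FALSE], t1)
  pf <- prevalence_filter(t2, min_samples = min_samples,
                          detection_threshold = detection_threshold)
  t3 <- pf$table
  t4 <- retable(as.data.frame(t3)[!t3$contaminant, , drop = FALSE], t3)
  t5 <- split_multi_orf(t4)
  report <- structure(
    list(n_input = n_input,
         n_after_isoform = nrow(t1),
         n_after_evidence = nrow(t2),
         n_after_prevalence = nrow(t3),
         n_after_contaminant = nrow(t4),
         n_after_split = nrow(t5),
         removed_signal_fraction = pf$removed_signal_fraction),
    class = "curation_report"
  )
  list(table = t5, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  cat(sprintf("  input isoforms:        %d\n", x$n_input))
  cat(sprintf("  longest isoform:       %d\n", x$n_after_isoform))
  cat(sprintf("  evidence filter:       %d\n", x$n_after_evidence))
  cat(sprintf("  prevalence filter:     %d (%.3g%% of signal removed)\n",
              x$n_after_prevalence, 100 * x$removed_signal_fraction))
  cat(sprintf("  contaminant removal:   %d\n", x$n_after_contaminant))
  cat(sprintf("  after multi-ORF split: %d\n", x$n_after_split))
  invisible(x)
}
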