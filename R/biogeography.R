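#' Relative abundance of a target taxon per sample
#'
#' Percent of retained reads assigned to the target taxon, where the
#' retained total excludes designated read groups (e.g. metazoan and plant
#' reads) before the ratio is taken.
#'
#' @param counts Long-format data frame with columns `sample_id`, `group`
#'   and `reads` (non-negative).
#' @param target_group Read group counted as the target taxon.
#' @param exclude_groups Character vector of groups removed from the
#'   denominator (default none).
#' @return Data frame with `sample_id`, `target_reads`, `retained_reads`
#'   and `percent`.
#' @export
relative_abundance <- function(counts, target_group,
                               exclude_groups = character()) {
  need <- c("sample_id", "group", "reads")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L) {
    stop(sprintf("counts table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (any(counts$reads < 0)) stop("read counts must be non-negative")
  if (target_group %in% exclude_groups) {
    stop("the target group cannot be excluded from the denominator")
  }
  keep <- !(counts$group %in% exclude_groups)
  samples <- unique(counts$sample_id)
  retained <- vapply(samples, function(s) {
    sum(counts$reads[keep & counts$sample_id == s])
  }, numeric(1))
  target <- vapply(samples, function(s) {
    sum(counts$reads[counts$sample_id == s & counts$group == target_group])
  }, numeric(1))
  zero <- retained == 0
  if (any(zero)) {
    stop(sprintf("zero retained reads in sample(s): %s",
                 paste(samples[zero], collapse = ", ")))
  }
  data.frame(sample_id = samples, target_reads = target,
             retained_reads = retained, percent = 100 * target / retained,
             stringsAsFactors = FALSE)
}

#' Bin per-sample relative abundances into an occupancy distribution
#'
#' Classifies percent abundances into the bins absent (exactly 0),
#' `(0, 0.1)`, `[0.1, 1)`, `[1, 10)` and `[10, Inf)` — edges closed on the
#' left, so a value of exactly 0.1 falls in the 0.1-1 bin — and reports the
#' percentage of samples per bin together with the mean and median
#' abundance.
#'
#' @param values Numeric vector of percent abundances (>= 0).
#' @return A list with `distribution_percent` (named numeric vector over
#'   the five bins, summing to 100), `n_samples`, `mean` and `median`.
#' @export
abundance_bins <- function(values) {
  if (length(values) == 0L) stop("'values' is empty")
  if (anyNA(values) || any(values < 0)) {
    stop("abundance values must be non-negative")
  }
  bins <- c("absent", "<0.1", "0.1-1", "1-10", ">10")
  cls <- ifelse(values == 0, "absent",
         ifelse(values < 0.1, "<0.1",
         ifelse(values < 1, "0.1-1",
         ifelse(values < 10, "1-10", ">10"))))
  tab <- table(factor(cls, levels = bins))
  dist <- 100 * as.numeric(tab) / length(values)
  names(dist) <- bins
  list(distribution_percent = dist,
       n_samples = length(values),
       mean = mean(values),
       median = stats::median(values))
}

#' Reads per million
#'
#' @param mapped_reads Reads mapped to the target reference (>= 0).
#' @param total_reads Total reads in the sample (> 0).
#' @return `1e6 * mapped_reads / total_reads`.
#' @export
rpm <- function(mapped_reads, total_reads) {
  if (any(total_reads <= 0)) stop("'total_reads' must be positive")
  if (any(mapped_reads < 0)) stop("'mapped_reads' must be non-negative")
  1e6 * mapped_reads / total_reads
}
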