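#' Write paired count series to a tab-separated file
#'
#' Long format with columns `time_h`, `organism`, `bottle`, `cells_per_ml`.
#'
#' @param series_list List of [count_series()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_count_series_tsv <- function(series_list, path) {
  if (inherits(series_list, "count_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s) {
    data.frame(time_h = s$time_h,
               organism = attr(s, "organism"),
               bottle = attr(s, "bottle"),
               cells_per_ml = s$cells_per_ml,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read count series from a tab-separated file
#'
#' @param path File written by [write_count_series_tsv()] (columns `time_h`,
#'   `organism`, `bottle`, `cells_per_ml`).
#' @return A list of [count_series()], one per organism x bottle
#'   combination, named `<organism>.<bottle>`.
#' @export
read_count_series_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("time_h", "organism", "bottle", "cells_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("count series file is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  groups <- split(df, interaction(df$organism, df$bottle, drop = TRUE))
  lapply(groups, function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    count_series(g$time_h, g$cells_per_ml, organism = g$organism[1],
                 bottle = g$bottle[1])
  })
}

#' Write a transcript or expression table as TSV
#'
#' @param table A data frame (e.g. a [transcript_table()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcript table from TSV
#'
#' @param path TSV with the [transcript_table()] columns.
#' @param sample_cols Names of the per-sample count columns; by default all
#'   columns not among the known metadata columns.
#' @return A [transcript_table()].
#' @export
read_transcript_table_tsv <- function(path, sample_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (is.null(sample_cols)) {
    meta <- c("transcript_id", "gene_id", "length", "genome_hit",
              "transcriptome_hit", "eukaryote_annotation", "contaminant",
              "orf_functions")
    sample_cols <- setdiff(names(df), meta)
  }
  transcript_table(df, sample_cols = sample_cols)
}

#' Write a JSON run manifest
#'
#' Records parameters, seed and any extra metadata of a run for provenance.
#'
#' @param params Named list of parameters (S3 parameter objects are
#'   flattened).
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest.
#' @return The path, invisibly.
#' @export
write_run_manifest <- function(params, path, extra = list()) {
  manifest <- c(lapply(params, unclass), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
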