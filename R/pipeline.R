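#' Default pipeline configuration
#'
#' All decision thresholds default to the values used throughout the
#' package: logFC > 2 and FDR < 1e-3 for differential calls, mean TPM > 500
#' for high expression, presence in at least 3 samples for the prevalence
#' filter, and a BH-adjusted cutoff of 0.05 for domain enrichment.
#'
#' @return Named list of defaults for every configurable field.
#' @export
config_defaults <- function() {
  list(
    stages = c("simulate", "kinetics", "curate", "de", "heg", "aggregate",
               "enrich"),
    seed = 1L,
    out_dir = ".",
    # kinetics
    window = "auto",
    prey_mean = "geometric",
    predator_mean = "integral",
    carbon_a = 0.216,
    carbon_b = 0.939,
    predator_esd = 4.1,
    prey_esd = 0.9,
    # curation
    min_samples = 3L,
    detection_threshold = 1,
    # expression
    logfc_threshold = 2,
    fdr_threshold = 1e-3,
    tpm_threshold = 500,
    # enrichment
    enrichment_cutoff = 0.05,
    # synthetic data
    n_genes = 2000L,
    replicates_per_phase = 3L,
    de_fraction = 0.1,
    log2fc_magnitude = 3,
    nb_dispersion = 0.1,
    count_noise_cv = 0.05
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file of key-value settings, fills every unset field with its
#' documented default ([config_defaults()]), and validates the result.
#' Unknown keys are an error (listing the valid ones), as are non-positive
#' thresholds.
#'
#' @param path Path to a YAML configuration file, or `NULL` for pure
#'   defaults.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown config key(s): %s\nvalid keys: %s",
                   paste(unknown, collapse = ", "),
                   paste(names(defaults), collapse = ", ")))
    }
  }
  config <- utils::modifyList(defaults, user)
  for (field in c("logfc_threshold", "fdr_threshold", "tpm_threshold",
                  "enrichment_cutoff", "carbon_a", "carbon_b",
                  "detection_threshold", "nb_dispersion")) {
    if (!is.numeric(config[[field]]) || config[[field]] <= 0) {
      stop(sprintf("config field '%s' must be a positive number", field))
    }
  }
  if (config$min_samples < 0) stop("'min_samples' must be non-negative")
  if (config$de_fraction < 0 || config$de_fraction > 1) {
    stop("'de_fraction' must lie in [0, 1]")
  }
  bad <- setdiff(config$stages, config_defaults()$stages)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  class(config) <- c("run_config", "list")
  config
}

#' Write a configuration to YAML
#'
#' @param config A `run_config` (or plain named list).
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# decorate a simulated expression table with curation structure: extra
# isoforms for some genes, evidence flags with a small contaminant fraction,
# and occasional chimeric two-ORF transcripts.
synthesize_transcript_table <- function(sim, seed,
                                        isoform_fraction = 0.2,
                                        contaminant_fraction = 0.02,
                                        chimera_fraction = 0.02) {
  set.seed(seed)
  counts <- sim$counts
  genes <- rownames(counts)
  n <- length(genes)
  df <- data.frame(transcript_id = paste0(genes, "_t1"),
                   gene_id = genes,
                   length = as.numeric(sim$lengths),
                   genome_hit = stats::runif(n) < 0.9,
                   transcriptome_hit = stats::runif(n) < 0.7,
                   eukaryote_annotation = stats::runif(n) < 0.8,
                   contaminant = stats::runif(n) < contaminant_fraction,
                   orf_functions = "func_a",
                   stringsAsFactors = FALSE)
  chim <- stats::runif(n) < chimera_fraction
  df$orf_functions[chim] <- "func_a;func_b"
  df <- cbind(df, as.data.frame(counts))
  # duplicate a fraction of genes as shorter secondary isoforms
  extra_idx <- which(stats::runif(n) < isoform_fraction)
  if (length(extra_idx) > 0L) {
    extra <- df[extra_idx, , drop = FALSE]
    extra$transcript_id <- paste0(genes[extra_idx], "_t2")
    extra$length <- pmax(200, round(extra$length * 0.6))
    df <- rbind(df, extra)
  }
  transcript_table(df, sample_cols = colnames(counts))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the selected stages in order on synthetic data generated from
#' the seeded simulators: batch-culture simulation, kinetics estimation,
#' transcriptome curation, differential expression, highly-expressed gene
#' selection, functional aggregation, and domain enrichment. Every stage
#' writes its outputs (TSV/JSON) under `out_dir` and contributes record
#' counts to the run report; rerunning with the same seed regenerates every
#' file identically.
#'
#' @param config A `run_config` from [load_config()].
#' @return A named list run report with per-stage summaries.
#' @export
run_pipeline <- function(config = load_config()) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (length(config$stages) == 0L) {
    warning("no stages selected; nothing to do")
    return(invisible(list()))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)
  state <- new.env(parent = emptyenv())

  run_stage <- list(
    simulate = function() {
      bp <- batch_culture_params(count_noise_cv = config$count_noise_cv,
                                 seed = config$seed)
      state$batch <- simulate_batch_culture(bp)
      state$batch_params <- bp
      ep <- expression_sim_params(
        n_genes = config$n_genes,
        replicates_per_phase = config$replicates_per_phase,
        de_fraction = config$de_fraction,
        log2fc_magnitude = config$log2fc_magnitude,
        nb_dispersion = config$nb_dispersion,
        seed = config$seed)
      state$expr <- simulate_expression(ep)
      write_count_series_tsv(list(state$batch$predator, state$batch$prey),
                             file.path(config$out_dir, "counts.tsv"))
      write_run_manifest(list(batch = bp, expression = ep),
                         file.path(config$out_dir, "manifest.json"))
      list(n_timepoints = nrow(state$batch$predator),
           n_genes = nrow(state$expr$counts),
           n_samples = ncol(state$expr$counts))
    },
    kinetics = function() {
      if (is.null(state$batch)) stop("kinetics needs the 'simulate' stage")
      pred <- state$batch$predator
      prey <- state$batch$prey
      win <- if (identical(config$window, "auto")) {
        select_exponential_window(pred)
      } else as.integer(strsplit(config$window, ":")[[1]])
      fit <- fit_log_linear(pred, win)
      gr <- grazing_estimate(prey, pred, win,
                             predator_growth_rate = fit$rate,
                             mean_method_prey = config$prey_mean,
                             mean_method_predator = config$predator_mean)
      cm <- carbon_model(config$carbon_a, config$carbon_b)
      ge <- growth_efficiency(fit$rate, gr$ingestion_rate,
                              cell_carbon_from_esd(config$predator_esd, cm),
                              cell_carbon_from_esd(config$prey_esd, cm))
      res <- list(growth_rate = fit$rate,
                  doubling_time_h = doubling_time(fit$rate),
                  r_squared = fit$r_squared,
                  window = win,
                  prey_decay_rate = gr$prey_decay_rate,
                  prey_mean = gr$prey_mean,
                  predator_mean = gr$predator_mean,
                  ingestion_rate = gr$ingestion_rate,
                  clearance_rate = gr$clearance_rate,
                  growth_efficiency = ge)
      jsonlite::write_json(res, file.path(config$out_dir, "kinetics.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    },
    curate = function() {
      if (is.null(state$expr)) stop("curate needs the 'simulate' stage")
      tab <- synthesize_transcript_table(state$expr, config$seed)
      cur <- curate_transcripts(tab, min_samples = config$min_samples,
                                detection_threshold = config$detection_threshold)
      state$curated <- cur$table
      samples <- attr(cur$table, "sample_cols")
      counts <- as.matrix(as.data.frame(cur$table)[, samples, drop = FALSE])
      rownames(counts) <- cur$table$gene_id
      state$tpm <- compute_tpm(counts, cur$table$length)
      write_table_tsv(cur$table, file.path(config$out_dir, "curated.tsv"))
      jsonlite::write_json(unclass(cur$report),
                           file.path(config$out_dir, "curation_report.json"),
                           auto_unbox = TRUE, digits = NA)
      unclass(cur$report)
    },
    de = function() {
      if (is.null(state$tpm)) stop("de needs the 'curate' stage")
      design <- state$expr$design
      res <- de_test(state$tpm, design, "exponential", "stationary")
      cls <- de_classify(res, logfc_threshold = config$logfc_threshold,
                         fdr_threshold = config$fdr_threshold)
      state$de <- cls
      write_table_tsv(cls, file.path(config$out_dir, "de_results.tsv"))
      as.list(attr(cls, "counts"))
    },
    heg = function() {
      if (is.null(state$tpm)) stop("heg needs the 'curate' stage")
      pm <- phase_mean(state$tpm, state$expr$design)
      state$phase_means <- pm
      heg <- highly_expressed_select(pm, threshold = config$tpm_threshold)
      state$heg <- heg
      part <- if (!is.null(state$de)) partition_heg(heg, state$de) else NULL
      writeLines(heg, file.path(config$out_dir, "heg_genes.txt"))
      c(list(n_heg = length(heg)),
        if (!is.null(part)) as.list(part$sizes))
    },
    aggregate = function() {
      if (is.null(state$phase_means)) stop("aggregate needs the 'heg' stage")
      genes <- if (length(state$heg) > 0) state$heg else
        rownames(state$phase_means)
      set.seed(config$seed + 2L)
      cmap <- data.frame(
        gene_id = genes,
        cellular_function = sample(paste0("function_", 1:6), length(genes),
                                   replace = TRUE),
        stringsAsFactors = FALSE)
      agg <- functional_aggregate(state$phase_means[genes, , drop = FALSE],
                                  cmap)
      write_table_tsv(agg, file.path(config$out_dir, "aggregate.tsv"))
      list(n_categories = nrow(agg))
    },
    enrich = function() {
      if (is.null(state$de)) stop("enrich needs the 'de' stage")
      background <- state$de$gene_id
      up <- state$de$gene_id[state$de$direction == "up_a"]
      if (length(up) < 2L) {
        return(list(n_enriched = 0L, note = "too few upregulated genes"))
      }
      ap <- annotation_sim_params(
        enriched_domains = "dom001", enrichment_bias = 25,
        seed = config$seed)
      ann <- simulate_annotations(ap, background, de_labels = up)
      enr <- domain_enrichment(up, background, ann,
                               adjusted_p_cutoff = config$enrichment_cutoff)
      write_table_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
      list(n_domains_tested = nrow(enr), n_enriched = sum(enr$enriched))
    }
  )

  for (stage in config$stages) {
    report[[stage]] <- run_stage[[stage]]()
  }
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
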