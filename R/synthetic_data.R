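#' Parameters for a synthetic batch-culture experiment
#'
#' Defines the latent predator-prey trajectories of a closed (batch) culture:
#' the predator (a bacterivorous flagellate) grows exponentially at rate
#' `predator_growth_rate` while the prey (bacteria) decays exponentially at
#' rate `prey_decay_rate`, until `exponential_end`; afterwards the prey is
#' constant and the predator declines at `stationary_decay_rate`. Observed
#' counts add multiplicative lognormal (or Poisson) observation noise on top
#' of the latent trajectory, emulating epifluorescence microscopy counts.
#'
#' The defaults reproduce the dynamics of a fast-growing marine flagellate on
#' a flavobacterial prey: mu = 0.16 h^-1 (doubling ~4.3 h), prey falling from
#' 2.5e7 cells mL^-1 at g ~ 0.058 h^-1 over a 34 h exponential phase, then a
#' slow stationary decline with a ~130 h half-life, and a counting CV of 5%.
#'
#' @param predator_growth_rate Predator specific growth rate mu, h^-1.
#' @param prey_decay_rate Prey exponential decay rate g, h^-1.
#' @param predator_init Initial predator abundance F1, cells mL^-1.
#' @param prey_init Initial prey abundance B1, cells mL^-1.
#' @param exponential_end End of the exponential phase, hours.
#' @param stationary_decay_rate Predator decay rate d after the exponential
#'   phase, h^-1.
#' @param dilution_factor Fold-dilution applied by [simulate_dilution()];
#'   must exceed 1 (default 20, i.e. 10 mL of culture into 190 mL).
#' @param count_noise_cv Coefficient of variation of the observation noise
#'   (fraction; 0 disables noise).
#' @param noise_model `"lognormal"` (default) or `"poisson"`.
#' @param sampling_times Strictly increasing sampling times, hours.
#' @param seed Integer seed for reproducibility.
#' @return An object of class `batch_culture_params`.
#' @seealso [simulate_batch_culture()], [simulate_dilution()]
#' @export
batch_culture_params <- function(predator_growth_rate = 0.16,
                                 prey_decay_rate = log(25 / 3.5) / 34,
                                 predator_init = 378,
                                 prey_init = 2.5e7,
                                 exponential_end = 34,
                                 stationary_decay_rate = log(2) / 130,
                                 dilution_factor = 20,
                                 count_noise_cv = 0.05,
                                 noise_model = c("lognormal", "poisson"),
                                 sampling_times = seq(0, 34, length.out = 9),
                                 seed = 1L) {
  noise_model <- match.arg(noise_model)
  rates <- c(predator_growth_rate = predator_growth_rate,
             prey_decay_rate = prey_decay_rate,
             stationary_decay_rate = stationary_decay_rate,
             count_noise_cv = count_noise_cv)
  bad <- names(rates)[rates < 0 | is.na(rates)]
  if (length(bad) > 0L) {
    stop(sprintf("negative or missing parameter(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (predator_init <= 0 || prey_init <= 0) {
    stop("initial abundances must be strictly positive")
  }
  if (length(sampling_times) == 0L) {
    stop("'sampling_times' is empty")
  }
  if (any(diff(sampling_times) <= 0)) {
    stop("'sampling_times' must be strictly increasing")
  }
  if (dilution_factor <= 1) {
    stop("'dilution_factor' must exceed 1")
  }
  structure(
    list(predator_growth_rate = predator_growth_rate,
         prey_decay_rate = prey_decay_rate,
         predator_init = predator_init,
         prey_init = prey_init,
         exponential_end = exponential_end,
         stationary_decay_rate = stationary_decay_rate,
         dilution_factor = dilution_factor,
         count_noise_cv = count_noise_cv,
         noise_model = noise_model,
         sampling_times = as.numeric(sampling_times),
         seed = as.integer(seed)),
    class = "batch_culture_params"
  )
}

# Latent (noiseless) batch-culture trajectories at arbitrary times.
latent_batch_trajectory <- function(params, times) {
  t_end <- params$exponential_end
  f_end <- params$predator_init * exp(params$predator_growth_rate * t_end)
  b_end <- params$prey_init * exp(-params$prey_decay_rate * t_end)
  predator <- ifelse(
    times <= t_end,
    params$predator_init * exp(params$predator_growth_rate * times),
    f_end * exp(-params$stationary_decay_rate * (times - t_end)))
  prey <- ifelse(
    times <= t_end,
    params$prey_init * exp(-params$prey_decay_rate * times),
    b_end)
  list(predator = predator, prey = prey)
}

# Observation noise around a latent trajectory. Lognormal noise is centred in
# log space (meanlog = log(latent)) so that log-linear rate estimates are
# unbiased; sdlog = sqrt(log(1 + cv^2)) gives a natural-scale CV equal to
# `cv`. Poisson mode treats the latent value as the expected count.
observe_counts <- function(latent, cv, noise_model) {
  if (noise_model == "poisson") {
    obs <- stats::rpois(length(latent), lambda = latent)
    return(pmax(obs, 0.5))  # guard against zero counts before log transform
  }
  if (cv == 0) return(latent)
  sdlog <- sqrt(log(1 + cv^2))
  latent * exp(stats::rnorm(length(latent), mean = 0, sd = sdlog))
}

#' Simulate a batch-culture predator-prey experiment
#'
#' Draws paired predator and prey count series from the piecewise-exponential
#' latent model of [batch_culture_params()] with multiplicative observation
#' noise. The latent model matches the assumptions of the kinetics
#' estimators, so a noiseless simulation followed by estimation recovers the
#' generating rates exactly.
#'
#' @param params A [batch_culture_params()].
#' @return A list with `predator` and `prey` [count_series()] objects and the
#'   `params` used.
#' @examples
#' sim <- simulate_batch_culture(batch_culture_params(count_noise_cv = 0))
#' fit_log_linear(sim$predator)$rate  # 0.16 exactly
#' @export
simulate_batch_culture <- function(params) {
  stopifnot(inherits(params, "batch_culture_params"))
  set.seed(params$seed)
  latent <- latent_batch_trajectory(params, params$sampling_times)
  pred_obs <- observe_counts(latent$predator, params$count_noise_cv,
                             params$noise_model)
  prey_obs <- observe_counts(latent$prey, params$count_noise_cv,
                             params$noise_model)
  list(
    predator = count_series(params$sampling_times, pred_obs,
                            organism = "flagellate"),
    prey = count_series(params$sampling_times, prey_obs,
                        organism = "bacteria"),
    params = params
  )
}

#' Simulate a dilution event during the exponential phase
#'
#' Both populations are divided by `dilution_factor` at `at_time`. In the
#' diluted bottle prey encounter rates drop below the level sustaining
#' predator growth: the predator keeps dividing at mu for at most
#' `post_dilution_divisions` doublings (on reserves ingested before the
#' dilution) and then declines at the stationary decay rate, while the prey
#' doubles at most once (at `prey_regrowth_rate`) and then stays constant.
#'
#' @param sim Output of [simulate_batch_culture()].
#' @param params A [batch_culture_params()] (noise and rates are reused).
#' @param at_time Dilution time in hours; must lie within the simulated
#'   sampling range.
#' @param post_dilution_divisions Maximum predator doublings after dilution
#'   (default 2).
#' @param sampling_times Post-dilution sampling times (hours, >= `at_time`);
#'   defaults to the original sampling times at or after `at_time`.
#' @param prey_regrowth_rate Prey growth rate after dilution, h^-1
#'   (default 0.07, a ~10 h doubling typical of marine bacteria in seawater).
#' @return A list with diluted `predator` and `prey` [count_series()].
#' @export
simulate_dilution <- function(sim, params, at_time,
                              post_dilution_divisions = 2,
                              sampling_times = NULL,
                              prey_regrowth_rate = 0.07) {
  stopifnot(inherits(params, "batch_culture_params"))
  rng <- range(params$sampling_times)
  if (at_time < rng[1] || at_time > rng[2]) {
    stop(sprintf("'at_time' = %g h lies outside the sampled range [%g, %g]",
                 at_time, rng[1], rng[2]))
  }
  if (is.null(sampling_times)) {
    sampling_times <- params$sampling_times[params$sampling_times >= at_time]
    if (length(sampling_times) == 0L || sampling_times[1] > at_time) {
      sampling_times <- c(at_time, sampling_times)
    }
  }
  if (any(sampling_times < at_time)) {
    stop("post-dilution 'sampling_times' must not precede 'at_time'")
  }
  latent0 <- latent_batch_trajectory(params, at_time)
  f0 <- latent0$predator / params$dilution_factor
  b0 <- latent0$prey / params$dilution_factor

  dt <- sampling_times - at_time
  mu <- params$predator_growth_rate
  f_cap <- f0 * 2^post_dilution_divisions
  t_cap <- if (mu > 0) post_dilution_divisions * log(2) / mu else 0
  predator <- ifelse(
    dt <= t_cap,
    f0 * exp(mu * dt),
    f_cap * exp(-params$stationary_decay_rate * (dt - t_cap)))
  b_cap <- 2 * b0
  t_bcap <- if (prey_regrowth_rate > 0) log(2) / prey_regrowth_rate else 0
  prey <- ifelse(dt <= t_bcap, b0 * exp(prey_regrowth_rate * dt), b_cap)

  set.seed(params$seed + 1L)
  pred_obs <- observe_counts(predator, params$count_noise_cv,
                             params$noise_model)
  prey_obs <- observe_counts(prey, params$count_noise_cv, params$noise_model)
  list(
    predator = count_series(sampling_times, pred_obs,
                            organism = "flagellate", bottle = "dilution"),
    prey = count_series(sampling_times, prey_obs,
                        organism = "bacteria", bottle = "dilution")
  )
}

#' Parameters for a synthetic phase-structured expression experiment
#'
#' Describes a negative-binomial bulk expression simulation over an ordered
#' set of growth phases (by default exponential, three starvation-by-dilution
#' states, and stationary), with gene-specific baseline means, a common
#' dispersion, and a fraction of genes given symmetric log2 fold-change
#' shifts between the first and last phase.
#'
#' @param n_genes Number of genes.
#' @param phases Ordered character vector of phase labels.
#' @param replicates_per_phase Samples per phase (>= 2; differential testing
#'   needs replication).
#' @param mean_log_tpm_range Range of log10 mean TPM from which gene
#'   baselines are drawn uniformly (default `c(0, 3)`, i.e. 1-1000 TPM).
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`); must be positive. Values near zero approach the
#'   Poisson limit.
#' @param de_fraction Fraction of genes with a planted fold change between
#'   the first and last phase, in `[0, 1]`.
#' @param log2fc_magnitude Magnitude of planted log2 fold changes.
#' @param transcript_length_range Range of transcript lengths in bases.
#' @param library_size Expected read count per sample.
#' @param seed Integer seed.
#' @return An object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 2000,
                                  phases = c("exponential", "dilution-1",
                                             "dilution-2", "dilution-3",
                                             "stationary"),
                                  replicates_per_phase = 3,
                                  mean_log_tpm_range = c(0, 3),
                                  nb_dispersion = 0.1,
                                  de_fraction = 0.1,
                                  log2fc_magnitude = 3,
                                  transcript_length_range = c(500, 5000),
                                  library_size = 5e6,
                                  seed = 1L) {
  if (n_genes < 1) stop("'n_genes' must be at least 1")
  if (nb_dispersion <= 0) stop("'nb_dispersion' must be positive")
  if (de_fraction < 0 || de_fraction > 1) {
    stop("'de_fraction' must lie in [0, 1]")
  }
  if (replicates_per_phase < 2) {
    stop("'replicates_per_phase' must be at least 2: differential testing needs replication")
  }
  if (length(phases) < 2) stop("at least two phases are required")
  structure(
    list(n_genes = as.integer(n_genes),
         phases = as.character(phases),
         replicates_per_phase = as.integer(replicates_per_phase),
         mean_log_tpm_range = mean_log_tpm_range,
         nb_dispersion = nb_dispersion,
         de_fraction = de_fraction,
         log2fc_magnitude = log2fc_magnitude,
         transcript_length_range = transcript_length_range,
         library_size = library_size,
         seed = as.integer(seed)),
    class = "expression_sim_params"
  )
}

#' Simulate a phase-structured negative-binomial expression matrix
#'
#' Gene baseline TPMs are drawn log-uniformly over `mean_log_tpm_range`;
#' a `de_fraction` of genes receive a `+/- log2fc_magnitude` shift between
#' the first and the last phase (half up in each direction, interpolated
#' linearly in log2 across intermediate phases, mimicking the gradual
#' transition from growth to starvation). Counts are negative binomial with
#' expected value proportional to TPM x transcript length, scaled to the
#' library size.
#'
#' @param params An [expression_sim_params()].
#' @return A list with `counts` (gene x sample integer matrix), `lengths`
#'   (named vector, bases), `design` (data frame `sample_id`, `phase`),
#'   `true_labels` (per gene: `"null"`, `"up_first"` or `"up_last"`) and
#'   `true_log2fc` (first vs last phase).
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "expression_sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  lengths <- round(stats::runif(n, params$transcript_length_range[1],
                                params$transcript_length_range[2]))
  names(lengths) <- gene_ids
  base_tpm <- 10^stats::runif(n, params$mean_log_tpm_range[1],
                              params$mean_log_tpm_range[2])

  n_de <- round(params$de_fraction * n)
  labels <- rep("null", n)
  true_lfc <- numeric(n)
  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    n_up_first <- ceiling(n_de / 2)
    up_first <- de_idx[seq_len(n_up_first)]
    up_last <- de_idx[-seq_len(n_up_first)]
    labels[up_first] <- "up_first"
    labels[up_last] <- "up_last"
    true_lfc[up_first] <- params$log2fc_magnitude
    true_lfc[up_last] <- -params$log2fc_magnitude
  }

  n_phase <- length(params$phases)
  reps <- params$replicates_per_phase
  design <- data.frame(
    sample_id = sprintf("%s_rep%d", rep(params$phases, each = reps),
                        rep(seq_len(reps), n_phase)),
    phase = rep(params$phases, each = reps),
    stringsAsFactors = FALSE
  )
  # per-phase log2 multiplier: +lfc/2 at first phase, -lfc/2 at last
  phase_pos <- seq(0, 1, length.out = n_phase)
  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
  size <- 1 / params$nb_dispersion
  for (j in seq_len(nrow(design))) {
    pos <- phase_pos[match(design$phase[j], params$phases)]
    tpm_j <- base_tpm * 2^(true_lfc * (0.5 - pos))
    rate <- tpm_j * lengths
    mu_j <- rate / sum(rate) * params$library_size
    counts[, j] <- stats::rnbinom(n, mu = mu_j, size = size)
  }
  list(counts = counts, lengths = lengths, design = design,
       true_labels = labels, true_log2fc = true_lfc, params = params)
}

#' Parameters for synthetic gene-to-domain annotations
#'
#' @param n_domains Number of distinct protein domains.
#' @param domains_per_gene Mean number of domain annotations per gene
#'   (Poisson-distributed per gene).
#' @param enriched_domains Character vector of domain labels planted as
#'   enriched in differentially expressed genes; must be a subset of
#'   `domain_labels`.
#' @param enrichment_bias Odds multiplier (>= 1) applied to the enriched
#'   domains when annotating differentially expressed genes.
#' @param domain_labels Labels for the domains (defaults to
#'   `dom001...`).
#' @param seed Integer seed.
#' @return An object of class `annotation_sim_params`.
#' @export
annotation_sim_params <- function(n_domains = 50,
                                  domains_per_gene = 2,
                                  enriched_domains = character(),
                                  enrichment_bias = 1,
                                  domain_labels = sprintf("dom%03d",
                                                          seq_len(n_domains)),
                                  seed = 1L) {
  if (n_domains < 1) stop("'n_domains' must be at least 1")
  if (enrichment_bias < 1) stop("'enrichment_bias' must be >= 1")
  if (domains_per_gene < 0) stop("'domains_per_gene' must be non-negative")
  if (!all(enriched_domains %in% domain_labels)) {
    stop("'enriched_domains' must be a subset of the domain labels")
  }
  structure(
    list(n_domains = as.integer(n_domains),
         domains_per_gene = domains_per_gene,
         enriched_domains = enriched_domains,
         enrichment_bias = enrichment_bias,
         domain_labels = domain_labels,
         seed = as.integer(seed)),
    class = "annotation_sim_params"
  )
}

#' Simulate gene-to-domain annotations with planted enrichment
#'
#' Each gene receives a Poisson number of domain annotations (mean
#' `domains_per_gene`, without replacement within a gene). For genes labelled
#' as differentially expressed, the sampling odds of the designated enriched
#' domains are multiplied by `enrichment_bias`; all other assignments are
#' uniform. With `enrichment_bias = 1` the differential genes are annotated
#' exactly like the background.
#'
#' @param params An [annotation_sim_params()].
#' @param genes Character vector of gene identifiers (nonempty).
#' @param de_labels Character vector naming the differentially expressed
#'   genes; every entry must appear in `genes`.
#' @return A data frame with columns `gene_id` and `domain_id` (one row per
#'   gene-domain assignment; a gene carries a domain at most once).
#' @export
simulate_annotations <- function(params, genes, de_labels = character()) {
  stopifnot(inherits(params, "annotation_sim_params"))
  if (length(genes) == 0L) stop("'genes' is empty")
  unknown <- setdiff(de_labels, genes)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown gene(s) in 'de_labels': %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  set.seed(params$seed)
  labels <- params$domain_labels
  base_w <- rep(1, length(labels))
  de_w <- base_w
  de_w[labels %in% params$enriched_domains] <- params$enrichment_bias
  is_de <- genes %in% de_labels

  n_assign <- stats::rpois(length(genes), params$domains_per_gene)
  n_assign <- pmin(n_assign, length(labels))
  keep <- n_assign > 0
  if (!any(keep)) {
    return(data.frame(gene_id = character(), domain_id = character(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(which(keep), function(i) {
    w <- if (is_de[i]) de_w else base_w
    data.frame(gene_id = genes[i],
               domain_id = sample(labels, n_assign[i], prob = w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
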