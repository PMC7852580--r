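# bacterivory

Quantitative analysis of bacterivorous heterotrophic flagellates grown in
batch culture on bacterial prey — the workhorse experiment for measuring
how marine protists graze bacteria — together with the expression-analysis
accounting that such growth studies pair with transcriptomics.

Heterotrophic flagellates are the main consumers of marine bacteria. In a
closed batch culture the flagellate grows exponentially at a specific rate
μ (h⁻¹) while the prey decays exponentially at rate *g*, then the culture
enters a stationary phase where the predator slowly declines. From paired
predator/prey cell-count time series the package estimates:

* **growth**: μ as the slope of ln(cells mL⁻¹) vs time over an
  automatically selected exponential window (longest contiguous window
  with R² ≥ 0.99); doubling time ln 2 / μ;
* **grazing** (Frost/Heinbokel): ingestion *I* = *g*·B̄/F̄ (bacteria
  flagellate⁻¹ h⁻¹) and clearance *C* = *g*/F̄ (mL flagellate⁻¹ h⁻¹),
  with geometric or time-integrated mean abundances B̄, F̄ — both
  conventions implemented and recorded;
* **growth efficiency**: GE = μ·C_F / (*I*·C_B), with per-cell carbon
  from equivalent spherical diameter via C = a·V^b;
* **survival**: stationary-phase half-life ln 2 / |decay slope|.

On the transcriptome side it implements curation with exact accounting
(longest isoform, evidence and contaminant filters, sample-prevalence
filter, multi-ORF splitting), TPM normalization, strict-threshold
differential-expression classification (|log2FC| > 2 and FDR < 10⁻³),
highly-expressed gene selection (mean TPM > 500 in any phase) and
partitioning, category-by-phase functional aggregation, and hypergeometric
protein-domain enrichment with Benjamini–Hochberg control. A seeded
synthetic-data module (batch-culture counts, negative-binomial expression
matrices, planted-enrichment annotations) makes every stage testable
without external data.

## Worked example

Simulate a batch culture under realistic defaults (μ = 0.16 h⁻¹, prey
falling from 2.5 × 10⁷ cells mL⁻¹, 5% counting noise, 9 timepoints over
34 h) and recover the kinetics:

```r
library(bacterivory)

params <- batch_culture_params(seed = 11)
sim <- simulate_batch_culture(params)

win <- select_exponential_window(sim$predator)
fit <- fit_log_linear(sim$predator, win)
fit
#> <growth_fit> rate 0.16198 h^-1, R^2 0.9994, window [1, 9] (9 points)
doubling_time(fit$rate)
#> 4.28 h

grazing_estimate(sim$prey, sim$predator, win,
                 predator_growth_rate = fit$rate)
#> <grazing_estimate> g = 0.05577 h^-1; B = 9.327e+06, F = 1.571e+04 cells mL^-1 (geometric/integral means)
#>   ingestion I = 33.1 bacteria flagellate^-1 h^-1; clearance C = 3.549e-06 mL flagellate^-1 h^-1

growth_efficiency(fit$rate, 33.1,
                  predator_carbon = cell_carbon_from_esd(4.4),
                  prey_carbon = cell_carbon_from_esd(0.85))
#> 0.502
```

The fitted rate (0.162 h⁻¹) recovers the generating 0.16 h⁻¹ within the
counting noise; the 4.28 h doubling time, ~0.056 h⁻¹ prey decay and ~33
bacteria flagellate⁻¹ h⁻¹ ingestion are the kind of numbers a fast
bacterivore produces in such cultures. The growth efficiency (here ~50%)
depends on the assumed cell sizes and carbon coefficients, which are
explicit arguments.

The full synthetic pipeline (simulation → kinetics → curation → DE →
highly-expressed selection → aggregation → enrichment) runs end to end
with one call and is byte-for-byte reproducible under a fixed seed:

```r
cfg <- load_config()          # all thresholds at their documented defaults
cfg$out_dir <- "run1"
report <- run_pipeline(cfg)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/bacterivory-cli.R` (subcommands `run`, `simulate`, `kinetics`,
`curate`, `de`, `heg`, `aggregate`, `enrich`).

## Documentation

The methods vignette (`vignettes/batch-culture-analysis.Rmd`) documents
the kinetic model and its assumptions, the curation and classification
rules, every tunable parameter with units and defaults, the statistical
design of the synthetic generators, and the package's known limitations.
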