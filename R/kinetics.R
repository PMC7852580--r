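#' Fit a log-linear growth (or decay) model to a count series
#'
#' Ordinary least squares of `ln(abundance)` on time over a window of
#' consecutive timepoints: the standard estimator of a specific growth or
#' decay rate from the linear part of logarithmic cell numbers versus time.
#' A positive slope is a specific growth rate (mu, h^-1); a negative slope is
#' an exponential decay rate.
#'
#' @param series A [count_series()].
#' @param window Integer `c(start, end)` row indices, or `NULL` for the full
#'   series.
#' @return An object of class `growth_fit`: a list with `rate` (h^-1),
#'   `intercept` (ln cells mL^-1 at t = 0), `r_squared`, `window` and
#'   `n_points`. For a perfectly constant series the slope is 0 and R^2 is
#'   undefined; it is reported as 0 by convention.
#' @examples
#' s <- count_series(0:3, c(100, 200, 400, 800))
#' fit_log_linear(s)$rate  # ln 2
#' @seealso [select_exponential_window()], [doubling_time()]
#' @export
fit_log_linear <- function(series, window = NULL) {
  sub <- series_window(series, window)
  if (nrow(sub) < 3L) {
    stop(sprintf("log-linear fit needs at least 3 points, got %d", nrow(sub)))
  }
  fit <- stats::lm(log(cells_per_ml) ~ time_h, data = sub)
  co <- stats::coef(fit)
  tss <- sum((log(sub$cells_per_ml) - mean(log(sub$cells_per_ml)))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::resid(fit)^2) / tss
  if (is.null(window)) window <- c(1L, nrow(series))
  structure(
    list(rate = unname(co[["time_h"]]),
         intercept = unname(co[["(Intercept)"]]),
         r_squared = r2,
         window = as.integer(window),
         n_points = nrow(sub)),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> rate %.5g h^-1, R^2 %.4f, window [%d, %d] (%d points)\n",
    x$rate, x$r_squared, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Select the exponential-phase window of a count series
#'
#' Finds the longest contiguous run of timepoints over which the log-linear
#' fit achieves `r_squared >= r2_threshold`, the operational definition of the
#' "linear part" of logarithmic cell numbers versus time. Ties on length are
#' broken toward the steeper absolute slope, then toward the earlier start,
#' so the selection is deterministic.
#'
#' @param series A [count_series()].
#' @param min_points Minimum number of points in a candidate window
#'   (default 4).
#' @param r2_threshold Minimum R^2 for a window to qualify (default 0.99,
#'   the goodness of fit expected of clean exponential growth).
#' @return Integer vector `c(start, end)` of row indices.
#' @export
select_exponential_window <- function(series, min_points = 4L,
                                      r2_threshold = 0.99) {
  stopifnot(inherits(series, "count_series"))
  n <- nrow(series)
  if (n < min_points) {
    stop(sprintf("series has %d points but min_points = %d", n, min_points))
  }
  best <- NULL
  for (start in seq_len(n - min_points + 1L)) {
    for (end in seq.int(start + min_points - 1L, n)) {
      f <- fit_log_linear(series, c(start, end))
      if (f$r_squared < r2_threshold) next
      cand <- list(len = end - start + 1L, slope = abs(f$rate), start = start,
                   window = c(start, end))
      if (is.null(best) ||
          cand$len > best$len ||
          (cand$len == best$len && cand$slope > best$slope) ||
          (cand$len == best$len && cand$slope == best$slope &&
           cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no window of >= %d points reaches R^2 >= %g; consider relaxing the threshold",
      min_points, r2_threshold))
  }
  as.integer(best$window)
}

#' Population doubling time from a specific growth rate
#'
#' @param rate Specific growth rate in h^-1; must be positive.
#' @return Doubling time in hours, `ln(2) / rate`.
#' @examples
#' doubling_time(0.16)  # ~4.33 h
#' @export
doubling_time <- function(rate) {
  if (!is.numeric(rate) || anyNA(rate) || any(rate <= 0)) {
    stop("doubling time is only defined for a positive growth rate")
  }
  log(2) / rate
}

#' Mean abundance between two timepoints of an exponential population
#'
#' Two conventions are in use for the average abundance entering grazing-rate
#' formulas: the geometric mean `sqrt(x_start * x_end)` and the time-averaged
#' (integral) mean of an exponential trajectory,
#' `(x_end - x_start) / ln(x_end / x_start)` (the logarithmic mean). Equal
#' endpoints return that common value under either method.
#'
#' @param x_start,x_end Abundances (cells mL^-1) at the window ends; positive.
#' @param method `"geometric"` or `"integral"`.
#' @return Mean abundance in cells mL^-1.
#' @examples
#' mean_abundance(25e6, 3.5e6, "geometric")  # 9.354e6
#' mean_abundance(25e6, 3.5e6, "integral")   # 10.935e6
#' @export
mean_abundance <- function(x_start, x_end,
                           method = c("geometric", "integral")) {
  method <- match.arg(method)
  if (!is.numeric(x_start) || !is.numeric(x_end) ||
      anyNA(c(x_start, x_end)) || x_start <= 0 || x_end <= 0) {
    stop("mean_abundance needs strictly positive endpoint abundances")
  }
  if (x_start == x_end) return(x_start)
  switch(method,
         geometric = sqrt(x_start * x_end),
         integral = (x_end - x_start) / log(x_end / x_start))
}

#' Frost/Heinbokel grazing estimate from paired predator and prey series
#'
#' Estimates bacterivory from a batch-culture window in which the predator
#' grows exponentially while the prey decays exponentially. The prey decay
#' coefficient `g` (h^-1) is minus the log-linear slope of the prey series
#' over the window. Ingestion is `I = g * B / F` (bacteria flagellate^-1
#' h^-1) and clearance `C = I / B = g / F` (mL flagellate^-1 h^-1), where `B`
#' and `F` are window-mean prey and predator abundances.
#'
#' Mean abundances can follow either convention (see [mean_abundance()]).
#' The default pairs a geometric prey mean with Heinbokel's integral predator
#' mean `(F_end - F_start) / (mu * dt)`, the correction for averaging over a
#' growing predator population; the latter needs the predator growth rate
#' `mu` and reduces to the logarithmic mean when growth is exactly
#' exponential at `mu`.
#'
#' @param prey,predator [count_series()] objects sampled at the same times.
#' @param window Integer `c(start, end)` row indices common to both series;
#'   `NULL` for the full range.
#' @param predator_growth_rate Predator specific growth rate mu (h^-1) over
#'   the window; required positive when `mean_method_predator = "integral"`.
#' @param mean_method_prey,mean_method_predator `"geometric"` or
#'   `"integral"`.
#' @return An object of class `grazing_estimate`: a list with
#'   `prey_decay_rate`, `prey_mean`, `predator_mean`, `ingestion_rate`,
#'   `clearance_rate`, the mean-method labels and the window.
#' @examples
#' tt <- c(0, 17, 34)
#' prey <- count_series(tt, 25e6 * exp(-log(25 / 3.5) / 34 * tt), "bacteria")
#' pred <- count_series(tt, 378 * exp(0.1575 * tt), "flagellate")
#' grazing_estimate(prey, pred, predator_growth_rate = 0.1575)
#' @export
grazing_estimate <- function(prey, predator, window = NULL,
                             predator_growth_rate = NULL,
                             mean_method_prey = c("geometric", "integral"),
                             mean_method_predator = c("integral", "geometric")) {
  mean_method_prey <- match.arg(mean_method_prey)
  mean_method_predator <- match.arg(mean_method_predator)
  prey_sub <- series_window(prey, window)
  pred_sub <- series_window(predator, window)
  if (nrow(prey_sub) != nrow(pred_sub) ||
      !isTRUE(all.equal(prey_sub$time_h, pred_sub$time_h))) {
    stop("prey and predator series must be sampled at the same times over the window")
  }
  prey_fit <- fit_log_linear(prey, window)
  g <- -prey_fit$rate
  if (g <= 0) {
    stop("no net grazing signal: prey abundance does not decline over the window")
  }
  dt <- prey_sub$time_h[nrow(prey_sub)] - prey_sub$time_h[1]
  b1 <- prey_sub$cells_per_ml[1]
  b2 <- prey_sub$cells_per_ml[nrow(prey_sub)]
  f1 <- pred_sub$cells_per_ml[1]
  f2 <- pred_sub$cells_per_ml[nrow(pred_sub)]

  prey_mean <- mean_abundance(b1, b2, mean_method_prey)
  if (mean_method_predator == "integral") {
    if (is.null(predator_growth_rate) || predator_growth_rate <= 0) {
      stop("the integral predator mean needs a positive 'predator_growth_rate'")
    }
    predator_mean <- (f2 - f1) / (predator_growth_rate * dt)
  } else {
    predator_mean <- mean_abundance(f1, f2, "geometric")
  }

  ingestion <- g * prey_mean / predator_mean
  clearance <- g / predator_mean
  if (is.null(window)) window <- c(1L, nrow(prey))
  structure(
    list(prey_decay_rate = g,
         prey_mean = prey_mean,
         predator_mean = predator_mean,
         ingestion_rate = ingestion,
         clearance_rate = clearance,
         mean_method_prey = mean_method_prey,
         mean_method_predator = mean_method_predator,
         window = as.integer(window)),
    class = "grazing_estimate"
  )
}

#' @export
print.grazing_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("<grazing_estimate> g = %.4g h^-1; B = %.4g, F = %.4g cells mL^-1",
           " (%s/%s means)\n  ingestion I = %.4g bacteria flagellate^-1 h^-1;",
           " clearance C = %.4g mL flagellate^-1 h^-1\n"),
    x$prey_decay_rate, x$prey_mean, x$predator_mean,
    x$mean_method_prey, x$mean_method_predator,
    x$ingestion_rate, x$clearance_rate))
  invisible(x)
}

#' Allometric cell-volume-to-carbon model
#'
#' Carbon per cell is modelled as `C = a * V^b` (pg C) with volume V in um^3,
#' the conventional power-law conversion for protists and bacteria. The
#' default coefficients a = 0.216 pg, b = 0.939 are conventional protist
#' values and can be overridden.
#'
#' @param coefficient_a Scale coefficient a in pg C (positive).
#' @param exponent_b Allometric exponent b (positive, dimensionless).
#' @return An object of class `carbon_model`.
#' @export
carbon_model <- function(coefficient_a = 0.216, exponent_b = 0.939) {
  if (coefficient_a <= 0 || exponent_b <= 0) {
    stop("carbon model coefficients must be positive")
  }
  structure(list(coefficient_a = coefficient_a, exponent_b = exponent_b),
            class = "carbon_model")
}

#' Carbon content per cell from equivalent spherical diameter
#'
#' Converts a microscope size measurement, expressed as the equivalent
#' spherical diameter (ESD), to cell carbon: the cell volume is
#' `V = (pi/6) * esd^3` (um^3) and carbon follows the allometric model
#' `a * V^b`.
#'
#' @param esd Equivalent spherical diameter in micrometres; positive.
#' @param model A [carbon_model()].
#' @return Carbon per cell in pg C.
#' @examples
#' cell_carbon_from_esd(2)  # ~0.83 pg with default coefficients
#' @export
cell_carbon_from_esd <- function(esd, model = carbon_model()) {
  stopifnot(inherits(model, "carbon_model"))
  if (!is.numeric(esd) || anyNA(esd) || any(esd <= 0)) {
    stop("ESD must be strictly positive")
  }
  volume <- pi / 6 * esd^3
  model$coefficient_a * volume^model$exponent_b
}

#' Gross growth efficiency of a bacterivorous predator
#'
#' The fraction of ingested prey carbon converted to predator biomass:
#' `GE = (mu * predator_carbon) / (ingestion * prey_carbon)`, with mu the
#' predator specific growth rate (h^-1), ingestion in prey cells
#' predator^-1 h^-1, and per-cell carbon contents in pg C.
#'
#' @param mu Predator specific growth rate (h^-1), non-negative.
#' @param ingestion Ingestion rate (prey cells predator^-1 h^-1), positive.
#' @param predator_carbon,prey_carbon Carbon per cell in pg C, positive.
#' @return Gross growth efficiency as a dimensionless fraction.
#' @export
growth_efficiency <- function(mu, ingestion, predator_carbon, prey_carbon) {
  if (!is.numeric(ingestion) || ingestion <= 0) {
    stop("growth efficiency needs a strictly positive ingestion rate")
  }
  if (predator_carbon <= 0 || prey_carbon <= 0) {
    stop("carbon contents must be strictly positive")
  }
  if (mu < 0) stop("'mu' must be non-negative")
  (mu * predator_carbon) / (ingestion * prey_carbon)
}

#' Half-life of an exponentially declining population
#'
#' Fits a log-linear decay over the window and returns
#' `t_1/2 = ln(2) / |slope|`, the survival half-life of a stationary-phase
#' population.
#'
#' @param series A [count_series()].
#' @param window Integer `c(start, end)` row indices, or `NULL`.
#' @return Half-life in hours.
#' @export
decay_half_life <- function(series, window = NULL) {
  fit <- fit_log_linear(series, window)
  if (fit$rate >= 0) {
    stop("population not declining: fitted slope is non-negative")
  }
  log(2) / abs(fit$rate)
}
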