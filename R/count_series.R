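#' Construct a cell-count time series
#'
#' A `count_series` holds timestamped cell abundances for one organism in one
#' culture bottle, the unit of input for all kinetics estimators. Times are in
#' hours and abundances in cells per mL. Zero or negative abundances are
#' rejected up front because every estimator works on log-transformed counts.
#'
#' @param times Numeric vector of sampling times in hours, strictly increasing.
#' @param abundances Numeric vector of cell abundances (cells mL^-1), strictly
#'   positive, same length as `times`.
#' @param organism Character label for the organism (e.g. `"flagellate"`,
#'   `"bacteria"`).
#' @param bottle Character label for the culture bottle.
#' @return An object of class `count_series`: a data frame with columns
#'   `time_h` and `cells_per_ml` and attributes `organism` and `bottle`.
#' @examples
#' fla <- count_series(c(0, 4, 8), c(100, 200, 400), organism = "flagellate")
#' fit_log_linear(fla)
#' @export
count_series <- function(times, abundances, organism = "organism",
                         bottle = "bottle-1") {
  if (length(times) == 0L) {
    stop("'times' is empty: a count series needs at least one sampling time")
  }
  if (length(times) != length(abundances)) {
    stop("'times' and 'abundances' must have the same length")
  }
  if (anyNA(times) || anyNA(abundances)) {
    stop("count series must not contain missing values")
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  bad <- which(abundances <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "abundances must be strictly positive; offending timepoint(s): %s h",
      paste(times[bad], collapse = ", ")
    ))
  }
  out <- data.frame(time_h = as.numeric(times),
                    cells_per_ml = as.numeric(abundances))
  attr(out, "organism") <- as.character(organism)
  attr(out, "bottle") <- as.character(bottle)
  class(out) <- c("count_series", "data.frame")
  out
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %s, bottle %s, %d timepoints (%g-%g h)\n",
              attr(x, "organism"), attr(x, "bottle"), nrow(x),
              min(x$time_h), max(x$time_h)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Subset a count series to a window of consecutive timepoints
#'
#' @param series A [count_series()].
#' @param window Integer vector `c(start, end)` of row indices (inclusive), or
#'   `NULL` for the full series.
#' @return A `count_series` restricted to the window.
#' @keywords internal
series_window <- function(series, window = NULL) {
  stopifnot(inherits(series, "count_series"))
  if (is.null(window)) return(series)
  if (length(window) != 2L || window[1] < 1L || window[2] > nrow(series) ||
      window[1] > window[2]) {
    stop(sprintf("invalid window [%s] for a series of %d points",
                 paste(window, collapse = ", "), nrow(series)))
  }
  idx <- seq.int(window[1], window[2])
  count_series(series$time_h[idx], series$cells_per_ml[idx],
               organism = attr(series, "organism"),
               bottle = attr(series, "bottle"))
}
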