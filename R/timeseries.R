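#' Uniformly sampled potential trace
#'
#' Light-weight container for a single-channel voltage recording: a start
#' time, a sampling rate and a numeric vector of differential potentials in
#' millivolts.  Sample `i` (1-based) sits at `t0 + (i - 1) / rate` seconds,
#' so the grid is uniform by construction.
#'
#' @param values Numeric vector of potentials, mV.  Must be finite.
#' @param rate Sampling rate, Hz.  Must be a single positive number.
#' @param t0 Start time of the first sample, seconds.
#' @param label Channel name, e.g. `"ChA"`.
#'
#' @return An object of class `osc_timeseries`.
#' @examples
#' ts <- osc_timeseries(sin(2 * pi * (0:99) / 50), rate = 1, label = "ChA")
#' ts_times(ts)[1:5]
#' @export
osc_timeseries <- function(values, rate, t0 = 0, label = "Ch") {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (s)", call. = FALSE)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite (no NA/NaN/Inf)", call. = FALSE)
  structure(
    list(t0 = t0, rate = rate, values = values, label = as.character(label)[1]),
    class = "osc_timeseries"
  )
}

#' Sample times of a trace
#'
#' @param ts An [osc_timeseries].
#' @return Numeric vector of timestamps in seconds, same length as the values.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "osc_timeseries"))
  ts$t0 + (seq_along(ts$values) - 1L) / ts$rate
}

#' @export
length.osc_timeseries <- function(x) length(x$values)

#' @export
print.osc_timeseries <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<osc_timeseries> %s: %d samples @ %g Hz, t0 = %g s\n",
              x$label, n, x$rate, x$t0))
  if (n > 0)
    cat(sprintf("  range [%.3f, %.3f] mV\n", min(x$values), max(x$values)))
  invisible(x)
}

# Internal: check two traces share the same sampling grid.
same_grid <- function(a, b, tol = 1e-9) {
  length(a$values) == length(b$values) &&
    abs(a$t0 - b$t0) < tol &&
    abs(a$rate - b$rate) < tol * max(a$rate, b$rate)
}
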