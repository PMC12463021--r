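#' Nyquist frequency of a sampling rate
#'
#' The highest frequency representable without aliasing: half the sampling
#' rate.
#'
#' @param rate Sampling rate, Hz (> 0).
#' @return Frequency in Hz.
#' @examples
#' nyquist_frequency(2.5)  # 1.25
#' @export
nyquist_frequency <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  rate / 2
}

#' Remove a linear trend by ordinary least squares
#'
#' Fits `value ~ time` by OLS and returns the residual trace together with
#' the fitted slope and intercept.  Residuals have zero mean by construction.
#'
#' @param ts An [osc_timeseries] with at least 2 samples.
#' @return A list of class `trend_fit` with elements `slope` (units/s),
#'   `intercept` (units, at t = 0), and `residual_series` (an
#'   [osc_timeseries]).
#' @examples
#' drifted <- add_linear_drift(
#'   generate_channel(channel_params("ChA", 35.94, 929.53), 2000, 1),
#'   slope = 0.01, intercept = 5)
#' fit <- linear_detrend(drifted)
#' fit$slope
#' @export
linear_detrend <- function(ts) {
  stopifnot(inherits(ts, "osc_timeseries"))
  if (length(ts$values) < 2L)
    stop("linear_detrend needs at least 2 samples", call. = FALSE)
  tt <- ts_times(ts)
  fit <- stats::lm.fit(cbind(1, tt), ts$values)
  coefs <- fit$coefficients
  res <- osc_timeseries(fit$residuals, rate = ts$rate, t0 = ts$t0,
                        label = ts$label)
  structure(
    list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
         residual_series = res),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope = %g /s, intercept = %g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Zero-phase low-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter.  A
#' cutoff at or above the Nyquist frequency of the trace is a documented
#' no-op that returns the input unchanged: the requested passband already
#' covers every representable frequency, so there is nothing to remove.
#' This makes configurations such as a 2 Hz cutoff on a 1 Hz-sampled
#' recording well-defined.
#'
#' @param ts An [osc_timeseries].
#' @param cutoff Cutoff frequency, Hz (> 0).
#' @param order Butterworth filter order (default 4; doubled effectively by
#'   the forward-backward pass).
#' @return A filtered [osc_timeseries] on the same grid.
#' @export
lowpass_filter <- function(ts, cutoff, order = 4) {
  stopifnot(inherits(ts, "osc_timeseries"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0)
    stop("`cutoff` must be a single positive number (Hz)", call. = FALSE)
  nyq <- nyquist_frequency(ts$rate)
  if (cutoff >= nyq) return(ts)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  v <- ts$values
  n <- length(v)
  # odd-reflection padding suppresses the forward-backward edge transient
  # (pad length scales with the filter's settling time at this cutoff)
  pad <- min(n - 1L, max(27L, ceiling(3 * ts$rate / cutoff)))
  if (pad > 0L) {
    left <- 2 * v[1] - v[seq(pad + 1L, 2L)]
    right <- 2 * v[n] - v[seq(n - 1L, n - pad)]
    filtered <- signal::filtfilt(bf, c(left, v, right))
    filtered <- filtered[(pad + 1L):(pad + n)]
  } else {
    filtered <- signal::filtfilt(bf, v)
  }
  osc_timeseries(filtered, rate = ts$rate, t0 = ts$t0, label = ts$label)
}
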