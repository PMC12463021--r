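#' Evaluate the damped-sinusoid channel model
#'
#' The channel model is \eqn{V(t) = A \sin(2\pi t / T + \phi)\, e^{-\alpha t}}
#' with amplitude `A` (mV), period `T` (s) and damping factor \eqn{\alpha}
#' (1/s).  With \eqn{\alpha \ge 0} the envelope never exceeds `A`, and
#' \eqn{\alpha = 0} gives an exact sinusoid.
#'
#' @param params A [channel_params].
#' @param t Time(s) since recording start, seconds (vectorised, all >= 0).
#' @param phase Phase offset in radians.  The model has no phase term, so the
#'   default is 0 (all channels start at zero crossing).
#' @return Potential(s) in mV, same length as `t`.
#' @examples
#' chE <- channel_params("ChE", 80.94, 724, alpha_per_s = 1.29e-6)
#' damped_sine_value(chE, t = 181)  # ~ A * exp(-alpha * T/4)
#' @export
damped_sine_value <- function(params, t, phase = 0) {
  stopifnot(inherits(params, "channel_params"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  params$amplitude_mV * sin(2 * pi * t / params$period_s + phase) *
    exp(-params$alpha_per_s * t)
}

#' Generate one synthetic channel
#'
#' Samples the damped-sinusoid model on the half-open uniform grid
#' `t = 0, 1/rate, 2/rate, ... < duration`, so a 10 000 s simulation at 1 Hz
#' yields exactly 10 000 samples.
#'
#' @param params A [channel_params].
#' @param duration Length of the recording, seconds (> 0).
#' @param rate Sampling rate, Hz (> 0).
#' @param phase Phase offset, radians (default 0).
#' @return An [osc_timeseries] labelled after the channel.
#' @examples
#' ch <- generate_channel(channel_params("ChB", 50.41, 299.88), 1000, 1)
#' length(ch)
#' @export
generate_channel <- function(params, duration, rate, phase = 0) {
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("`duration` must be a single positive number (s)", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1L) / rate
  osc_timeseries(damped_sine_value(params, t, phase), rate = rate,
                 t0 = 0, label = params$label)
}

#' Generate a full multichannel ensemble
#'
#' One synthetic trace per preset channel on a common grid, all at phase 0,
#' using each channel's own amplitude, period and damping factor.
#'
#' @param preset An [ensemble_preset] (or named list of [channel_params]).
#' @param duration Length of the recording, seconds (> 0).
#' @param rate Sampling rate in Hz, or `"default"` to use the preset's rate.
#' @param alpha_per_s Optional common damping override, 1/s; `NULL` (default)
#'   keeps each channel's own value.
#' @return Named list of [osc_timeseries], one per channel.
#' @examples
#' ens <- generate_ensemble(ensemble_preset("pure_algae"), duration = 1000)
#' names(ens)
#' @export
generate_ensemble <- function(preset, duration, rate = "default",
                              alpha_per_s = NULL) {
  channels <- if (inherits(preset, "ensemble_preset")) preset$channels
              else preset
  if (identical(rate, "default")) {
    if (!inherits(preset, "ensemble_preset"))
      stop('rate = "default" needs an ensemble_preset', call. = FALSE)
    rate <- preset$default_rate
  }
  lapply(channels, function(p) {
    if (!is.null(alpha_per_s))
      p <- channel_params(p$label, p$amplitude_mV, p$period_s,
                          alpha_per_s, p$n_peaks)
    generate_channel(p, duration, rate)
  })
}

#' Add Gaussian noise to a trace
#'
#' Adds independent Gaussian perturbations with standard deviation
#' `sd_fraction * reference_amplitude` to every sample, emulating
#' environmental noise expressed as a fraction of a channel's nominal
#' amplitude.  The same `seed` with the same inputs gives a bit-identical
#' result; the generator state of the caller is left untouched.
#'
#' @param ts An [osc_timeseries].
#' @param sd_fraction Noise SD as a fraction of `reference_amplitude` (>= 0).
#' @param reference_amplitude Reference amplitude, mV (> 0).  Use the
#'   channel's nominal (undamped) model amplitude.
#' @param seed Integer seed for the noise stream.
#' @return A new [osc_timeseries] on the same grid.
#' @examples
#' ts <- generate_channel(channel_params("ChB", 50.41, 299.88), 1000, 1)
#' noisy <- add_gaussian_noise(ts, 0.1, reference_amplitude = 50.41, seed = 1)
#' @export
add_gaussian_noise <- function(ts, sd_fraction, reference_amplitude, seed) {
  stopifnot(inherits(ts, "osc_timeseries"))
  if (!is.numeric(sd_fraction) || length(sd_fraction) != 1L ||
      !is.finite(sd_fraction) || sd_fraction < 0)
    stop("`sd_fraction` must be a single number >= 0", call. = FALSE)
  if (!is.numeric(reference_amplitude) || length(reference_amplitude) != 1L ||
      !is.finite(reference_amplitude) || reference_amplitude <= 0)
    stop("`reference_amplitude` must be a single positive number", call. = FALSE)
  if (sd_fraction == 0) return(ts)
  # seed a private stream and restore the caller's RNG state afterwards
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eps <- stats::rnorm(length(ts$values),
                      sd = sd_fraction * reference_amplitude)
  osc_timeseries(ts$values + eps, rate = ts$rate, t0 = ts$t0,
                 label = ts$label)
}

#' Add a linear baseline drift
#'
#' Adds `intercept + slope * t` to every sample, emulating the slow baseline
#' drift that environmental factors impose on long recordings.
#'
#' @param ts An [osc_timeseries].
#' @param slope Drift slope, mV/s.
#' @param intercept Baseline offset, mV.
#' @return A new [osc_timeseries] on the same grid.
#' @export
add_linear_drift <- function(ts, slope, intercept = 0) {
  stopifnot(inherits(ts, "osc_timeseries"))
  tt <- ts_times(ts)
  osc_timeseries(ts$values + intercept + slope * tt,
                 rate = ts$rate, t0 = ts$t0, label = ts$label)
}
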