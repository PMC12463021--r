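#' Gate error rate under Gaussian noise
#'
#' Monte Carlo estimate of how often additive Gaussian noise flips a gate's
#' output.  The clean pipeline generates zero-phase damped sinusoids for the
#' two channels, binarizes them at half their nominal amplitudes, and
#' evaluates the gate.  The noisy pipeline adds independent Gaussian noise
#' to each analog channel (SD = `noise_sd_fraction` times that channel's
#' nominal amplitude) before binarization; both pipelines share the same
#' deterministic signal so the comparison isolates the noise.  The error
#' rate is the fraction of samples where the two outputs differ.
#'
#' @param preset An [ensemble_preset].
#' @param channelA,channelB Channel labels (only `channelA` is used for the
#'   unary `NOT`).
#' @param gate Gate name (see [eval_gate()]).
#' @param noise_sd_fraction Noise SD as a fraction of channel amplitude
#'   (default 0.1, i.e. 10%).
#' @param duration Simulation length, s (default 10000).
#' @param rate Sampling rate, Hz, or `"default"`.
#' @param seed Integer seed; the two channels draw from distinct streams
#'   derived from it, and identical seeds give bit-identical results.
#' @param alpha_per_s Common damping factor (default `1e-6` 1/s).
#' @return A list of class `error_rate_result`: `gate`, `noise_sd_fraction`,
#'   `error_rate`, `n_samples`, `seed`.
#' @examples
#' gate_error_rate(ensemble_preset("pure_algae"), gate = "NOT",
#'                 duration = 1000, seed = 1)
#' @export
gate_error_rate <- function(preset, channelA = "ChA", channelB = "ChB",
                            gate = "AND", noise_sd_fraction = 0.1,
                            duration = 10000, rate = "default", seed = 1,
                            alpha_per_s = 1e-6) {
  stopifnot(inherits(preset, "ensemble_preset"))
  gate <- match.arg(toupper(gate), .gate_kinds)
  if (noise_sd_fraction < 0)
    stop("`noise_sd_fraction` must be >= 0", call. = FALSE)
  if (identical(rate, "default")) rate <- preset$default_rate
  seed <- as.integer(seed)

  clean_and_noisy <- function(label, sub_seed) {
    p <- preset$channels[[label]]
    if (is.null(p)) stop("channel not in preset: ", label, call. = FALSE)
    clean <- generate_channel(
      channel_params(p$label, p$amplitude_mV, p$period_s, alpha_per_s),
      duration, rate)
    noisy <- add_gaussian_noise(clean, noise_sd_fraction,
                                reference_amplitude = p$amplitude_mV,
                                seed = sub_seed)
    spec <- threshold_spec("half_amplitude",
                           reference_amplitude = p$amplitude_mV)
    list(clean = binarize(clean, spec), noisy = binarize(noisy, spec))
  }

  a <- clean_and_noisy(channelA, seed)
  if (gate == "NOT") {
    clean_out <- eval_gate(gate, a$clean)$output$states
    noisy_out <- eval_gate(gate, a$noisy)$output$states
  } else {
    # distinct stream per channel, derived deterministically from `seed`
    b <- clean_and_noisy(channelB, seed + 1000003L)
    clean_out <- eval_gate(gate, a$clean, b$clean)$output$states
    noisy_out <- eval_gate(gate, a$noisy, b$noisy)$output$states
  }
  structure(
    list(gate = gate, noise_sd_fraction = noise_sd_fraction,
         error_rate = mean(clean_out != noisy_out),
         n_samples = length(clean_out), seed = seed),
    class = "error_rate_result"
  )
}

#' @export
print.error_rate_result <- function(x, ...) {
  cat(sprintf(
    "<error_rate_result> %s: error rate %.4f (noise SD %.0f%%, n = %d, seed %d)\n",
    x$gate, x$error_rate, 100 * x$noise_sd_fraction, x$n_samples, x$seed))
  invisible(x)
}

#' Error rates for a set of gates
#'
#' Convenience wrapper running [gate_error_rate()] over several gates, with
#' an optional replicate mode averaging over derived seeds.
#'
#' @inheritParams gate_error_rate
#' @param gates Character vector of gate names (default all seven).
#' @param replicates Number of independent noise draws per gate (default 1).
#' @return Data frame with columns `gate`, `noise_sd_fraction`,
#'   `error_rate`, and (when `replicates > 1`) `se`.
#' @export
gate_error_table <- function(preset, channelA = "ChA", channelB = "ChB",
                             gates = .gate_kinds, noise_sd_fraction = 0.1,
                             duration = 10000, rate = "default", seed = 1,
                             replicates = 1) {
  rows <- lapply(gates, function(g) {
    ers <- vapply(seq_len(replicates), function(r) {
      gate_error_rate(preset, channelA, channelB, gate = g,
                      noise_sd_fraction = noise_sd_fraction,
                      duration = duration, rate = rate,
                      seed = seed + (r - 1L) * 7919L)$error_rate
    }, numeric(1))
    out <- data.frame(gate = g, noise_sd_fraction = noise_sd_fraction,
                      error_rate = mean(ers))
    if (replicates > 1) out$se <- stats::sd(ers) / sqrt(replicates)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two traces
#'
#' Standard product-moment correlation on the common sampling grid.
#'
#' @param x,y [osc_timeseries] on the same grid, each non-constant, with at
#'   least 2 samples.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(inherits(x, "osc_timeseries"), inherits(y, "osc_timeseries"))
  if (!same_grid(x, y))
    stop("series must share the same sampling grid", call. = FALSE)
  if (length(x$values) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0)
    stop("correlation undefined for constant series", call. = FALSE)
  stats::cor(x$values, y$values)
}

#' Pairwise correlation matrix of a model ensemble
#'
#' Generates the preset's zero-phase damped-sinusoid ensemble and computes
#' all pairwise Pearson correlations of the analog (not binarized) traces.
#'
#' @param preset An [ensemble_preset].
#' @param duration Simulation length, s (default 10000).
#' @param rate Sampling rate, Hz, or `"default"`.
#' @param alpha_per_s Common damping factor (default `1e-6` 1/s).
#' @return A symmetric numeric matrix with unit diagonal, dimnames set to
#'   the channel labels.
#' @examples
#' cm <- correlation_matrix(ensemble_preset("pure_algae"), duration = 2000)
#' cm["ChC", "ChF"]
#' @export
correlation_matrix <- function(preset, duration = 10000, rate = "default",
                               alpha_per_s = 1e-6) {
  series <- generate_ensemble(preset, duration, rate,
                              alpha_per_s = alpha_per_s)
  mat <- sapply(series, function(ts) ts$values)
  cm <- stats::cor(mat)
  dimnames(cm) <- list(names(series), names(series))
  cm
}
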