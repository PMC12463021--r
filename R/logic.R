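#' Binarization threshold specification
#'
#' A threshold for mapping an analog trace to a 0/1 signal.  Two
#' conventions are supported: a fixed voltage (`fixed`, e.g. the 50 mV
#' threshold used for illustrating gate waveforms) and half of a channel's
#' nominal amplitude (`half_amplitude`, the convention behind the reported
#' gate high-state frequencies).
#'
#' @param mode `"fixed"` or `"half_amplitude"`.
#' @param theta Threshold in mV (used when `mode = "fixed"`).
#' @param reference_amplitude Channel amplitude in mV (used when
#'   `mode = "half_amplitude"`; the resolved threshold is half of it).
#' @return An object of class `threshold_spec`.
#' @examples
#' threshold_spec("fixed", theta = 50)
#' threshold_spec("half_amplitude", reference_amplitude = 50.41)
#' @export
threshold_spec <- function(mode = c("fixed", "half_amplitude"),
                           theta = NULL, reference_amplitude = NULL) {
  mode <- match.arg(mode)
  resolved <- switch(mode,
    fixed = {
      if (is.null(theta)) stop('`theta` required for mode "fixed"',
                               call. = FALSE)
      theta
    },
    half_amplitude = {
      if (is.null(reference_amplitude))
        stop('`reference_amplitude` required for mode "half_amplitude"',
             call. = FALSE)
      reference_amplitude / 2
    }
  )
  if (!is.numeric(resolved) || length(resolved) != 1L ||
      !is.finite(resolved) || resolved <= 0)
    stop("resolved threshold must be a single positive number (mV)",
         call. = FALSE)
  structure(list(mode = mode, theta_mV = resolved), class = "threshold_spec")
}

#' Binarize a trace at a threshold
#'
#' Maps each sample to 1 when the potential is at or above the resolved
#' threshold (inclusive at equality) and 0 otherwise.
#'
#' @param ts An [osc_timeseries].
#' @param spec A [threshold_spec].
#' @return An object of class `binary_signal`: `t0`, `rate`, integer
#'   `states` in \{0, 1\}, `threshold_mV`, `source_label`.
#' @examples
#' ts <- generate_channel(channel_params("ChB", 50.41, 299.88), 1000, 1)
#' bs <- binarize(ts, threshold_spec("half_amplitude",
#'                                   reference_amplitude = 50.41))
#' mean(bs$states)
#' @export
binarize <- function(ts, spec) {
  stopifnot(inherits(ts, "osc_timeseries"), inherits(spec, "threshold_spec"))
  structure(
    list(t0 = ts$t0, rate = ts$rate,
         states = as.integer(ts$values >= spec$theta_mV),
         threshold_mV = spec$theta_mV, source_label = ts$label),
    class = "binary_signal"
  )
}

#' @export
print.binary_signal <- function(x, ...) {
  cat(sprintf(
    "<binary_signal> %s @ %g mV: %d samples, high fraction %.3f\n",
    x$source_label, x$threshold_mV, length(x$states), mean(x$states)))
  invisible(x)
}

.gate_kinds <- c("AND", "OR", "NOT", "XOR", "NAND", "NOR", "XNOR")

.apply_gate <- function(gate, a, b = NULL) {
  switch(gate,
    AND  = a & b,
    OR   = a | b,
    NOT  = !a,
    XOR  = xor(a, b),
    NAND = !(a & b),
    NOR  = !(a | b),
    XNOR = !xor(a, b),
    stop("unknown gate: ", gate, call. = FALSE)
  )
}

#' Evaluate a Boolean gate on binary signals
#'
#' Applies one of the seven standard gates sample-wise.  `NOT` is unary
#' (operand `a` only); all other gates need two signals on the same grid.
#' The result records the high-state frequency: the fraction of output
#' samples equal to 1.
#'
#' @param gate One of `"AND"`, `"OR"`, `"NOT"`, `"XOR"`, `"NAND"`, `"NOR"`,
#'   `"XNOR"`.
#' @param a,b `binary_signal` operands (`b` must be absent for `NOT`).
#' @return An object of class `gate_result`: `gate`, `output` (a
#'   `binary_signal`), and `high_state_frequency`.
#' @export
eval_gate <- function(gate, a, b = NULL) {
  gate <- match.arg(toupper(gate), .gate_kinds)
  stopifnot(inherits(a, "binary_signal"))
  if (gate == "NOT") {
    if (!is.null(b))
      stop("NOT is unary: do not supply `b`", call. = FALSE)
    out <- .apply_gate(gate, a$states == 1L)
  } else {
    if (is.null(b) || !inherits(b, "binary_signal"))
      stop(gate, " needs two binary_signal operands", call. = FALSE)
    if (length(a$states) != length(b$states) ||
        abs(a$t0 - b$t0) > 1e-9 || abs(a$rate - b$rate) > 1e-9 * a$rate)
      stop("operands must share the same sampling grid", call. = FALSE)
    out <- .apply_gate(gate, a$states == 1L, b$states == 1L)
  }
  output <- structure(
    list(t0 = a$t0, rate = a$rate, states = as.integer(out),
         threshold_mV = NA_real_,
         source_label = paste0(gate, "(", a$source_label,
                               if (gate != "NOT") paste0(",", b$source_label),
                               ")")),
    class = "binary_signal"
  )
  structure(
    list(gate = gate, output = output,
         high_state_frequency = mean(output$states)),
    class = "gate_result"
  )
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %s: high-state frequency %.3f over %d samples\n",
              x$gate, x$high_state_frequency, length(x$output$states)))
  invisible(x)
}

#' Truth table of a gate
#'
#' Exhaustive enumeration of the gate over all input combinations: 4 rows
#' for binary gates, 2 for `NOT`.
#'
#' @param gate Gate name (see [eval_gate()]).
#' @return A data frame with columns `a`, `b` (absent for `NOT`) and `out`,
#'   all 0/1 integers.
#' @examples
#' truth_table("NOR")
#' @export
truth_table <- function(gate) {
  gate <- match.arg(toupper(gate), .gate_kinds)
  if (gate == "NOT") {
    a <- c(0L, 1L)
    data.frame(a = a, out = as.integer(.apply_gate(gate, a == 1L)))
  } else {
    g <- expand.grid(b = c(0L, 1L), a = c(0L, 1L))[, c("a", "b")]
    g <- g[order(g$a, g$b), ]
    rownames(g) <- NULL
    g$out <- as.integer(.apply_gate(gate, g$a == 1L, g$b == 1L))
    g
  }
}

#' Gate high-state frequencies for a channel pair
#'
#' Reproduces the deterministic gate-frequency experiment: generate
#' zero-phase damped sinusoids for two preset channels, binarize each
#' (half-amplitude threshold by default, using the channel's nominal model
#' amplitude as reference), evaluate all seven gates (`NOT` acts on channel
#' A), and report each gate's high-state frequency.
#'
#' @param preset An [ensemble_preset].
#' @param channelA,channelB Channel labels present in the preset.
#' @param duration Simulation length, s (default 10000).
#' @param rate Sampling rate, Hz, or `"default"` for the preset's rate.
#' @param threshold `"half_amplitude"` (default) or a fixed threshold in mV.
#' @param alpha_per_s Common damping factor (default `1e-6` 1/s).
#' @return Named numeric vector of high-state frequencies, one per gate.
#' @examples
#' gate_frequency_experiment(ensemble_preset("pure_algae"), "ChA", "ChB",
#'                           duration = 1000)
#' @export
gate_frequency_experiment <- function(preset, channelA = "ChA",
                                      channelB = "ChB", duration = 10000,
                                      rate = "default",
                                      threshold = "half_amplitude",
                                      alpha_per_s = 1e-6) {
  stopifnot(inherits(preset, "ensemble_preset"))
  for (ch in c(channelA, channelB))
    if (!ch %in% names(preset$channels))
      stop("channel not in preset: ", ch, call. = FALSE)
  if (identical(rate, "default")) rate <- preset$default_rate
  pa <- preset$channels[[channelA]]
  pb <- preset$channels[[channelB]]

  spec_for <- function(p) {
    if (identical(threshold, "half_amplitude"))
      threshold_spec("half_amplitude", reference_amplitude = p$amplitude_mV)
    else
      threshold_spec("fixed", theta = threshold)
  }
  gen <- function(p) {
    generate_channel(
      channel_params(p$label, p$amplitude_mV, p$period_s, alpha_per_s),
      duration, rate)
  }
  ia <- binarize(gen(pa), spec_for(pa))
  ib <- binarize(gen(pb), spec_for(pb))

  vapply(.gate_kinds, function(g) {
    if (g == "NOT") eval_gate(g, ia)$high_state_frequency
    else eval_gate(g, ia, ib)$high_state_frequency
  }, numeric(1))
}
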