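---
title: "From bioelectric oscillations to Boolean logic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bioelectric oscillations to Boolean logic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillogic)
```

## The problem

Cultures of the coccolithophore microalga *Emiliania huxleyi* — on their own
or mixed with glutamic-acid:phenylalanine proteinoid microspheres — produce
slow, spontaneous electrical oscillations that can be picked up on
multichannel voltage loggers: periods of minutes to hours, amplitudes of
tens to hundreds of millivolts, superimposed on a drifting baseline.
`oscillogic` provides the full processing chain for such recordings:

1. a **synthetic generator** producing multichannel recordings with the
   statistical structure the analysis assumes,
2. **oscillation metrics** — peak detection and per-channel summary
   statistics,
3. a **logic engine** — threshold binarization and the seven standard
   Boolean gates evaluated sample-wise,
4. **robustness analysis** — gate error rates under Gaussian noise and
   cross-channel Pearson correlation, and
5. plain-text **I/O** plus a reproducible report runner.

## The channel model

Each channel is modelled as a damped sinusoid

$$V(t) = A \sin\!\left(\frac{2\pi t}{T}\right) e^{-\alpha t},$$

with mean amplitude $A$ (mV), mean period $T$ (s) and damping factor
$\alpha$ (1/s). The model has no phase term, so every channel starts at its
zero crossing at $t = 0$; a `phase` argument exists for experimentation but
defaults to 0. This zero-phase convention is a modelling choice — real
recordings have unknown per-channel phases — but it is the convention under
which the reported gate frequencies are reproducible, so it is the package
default. The default damping $\alpha = 10^{-6}\,\mathrm{s^{-1}}$ keeps the
envelope within 1% of nominal over a 10 000 s simulation, i.e. oscillations
are effectively sustained on that horizon.

Two presets carry the published per-channel parameters of the studied
systems, eight channels each (`ChA`–`ChH`):

```{r presets}
ensemble_preset("pure_algae")
```

The pure-algae system samples at 1 Hz, the algae–proteinoid mixture at
2.5 Hz. Simulations use a half-open time grid $t \in \{0, 1/f_s, \dots\} <
D$, so "10 000 s at 1 Hz" is exactly 10 000 samples and "10 000 s at
2.5 Hz" exactly 25 000 — matching the reported sample counts.

## Oscillation metrics

The per-channel statistics are defined on detected extrema:

* cycle periods $T_i = t_{\mathrm{peak},i+1} - t_{\mathrm{peak},i}$,
* cycle amplitudes $A_j$ = peak value minus the lowest trough between that
  peak and the next,
* mean period $\bar T$ and mean amplitude $\bar A$,
* amplitude spread $\sigma_A$ with **population** divisor $N$ (the defining
  formula uses $1/N$, and the package follows it literally),
* frequency $f = 1/\bar T$ and power $P = f \bar A^2$, both computed at full
  precision with no intermediate rounding, so the identity
  $P = \bar A^2/\bar T$ holds exactly on every summary.

Peaks must clear three gates, with defaults matching the recording
analysis: minimum height 10 mV, minimum topographic prominence 5 mV and
minimum mutual separation 100 s. Prominence is the height of a peak above
the higher of the two valleys separating it from higher terrain (or the
record edge). When two candidates fall within the separation window the
higher wins, and at equal height the earlier one — a deterministic,
documented tie-break. Troughs are detected on the negated trace with
prominence and separation only: recordings can sit on a negative baseline,
where a fixed positive height requirement on minima would be meaningless.
An optional symmetric gate (`trough_height_gate = TRUE`) is available.

The defining "cycle" for amplitudes is taken as the peak-to-next-peak span.
The 100 s figure quoted alongside the amplitude definition is retained as
the extrema separation threshold rather than as a window length; with
periods of 250 s and up, every cycle then contains at least one trough.

```{r metrics}
ts <- generate_channel(channel_params("demo", 80, 500, 0), 5000, 1)
analyze_channel(ts, detrend = FALSE)$summary
```

### Pre-processing

`linear_detrend()` removes an ordinary-least-squares line, mirroring the
baseline correction applied to recorded (not synthetic) data; residuals
have zero mean by construction. One numerical fact worth knowing: a
sinusoid is orthogonal to a *constant* over whole periods but not to *t*,
so detrending a pure sine of amplitude $A$ and period $T$ over duration $D$
fits a small nonzero slope, $-6AT/(\pi D^2)$ in closed form. The bias
decays as $1/D^2$ and is negligible at recording lengths, but tests of the
detrender assert the closed form rather than pretending the slope is zero.

`lowpass_filter()` is a zero-phase (forward–backward) Butterworth filter,
order 4 by default. Two numerical choices:

* A cutoff at or above the Nyquist frequency is a **documented no-op**: the
  requested passband already covers every representable frequency. This
  makes a "2 Hz cutoff on 1 Hz-sampled data" configuration well-defined as
  the identity instead of an error.
* The input is padded by odd reflection (pad length about three filter time
  constants at the cutoff) before filtering and trimmed after, suppressing
  the start/end transients a plain forward–backward pass would leave; a
  constant trace passes through unchanged to within 1e-6.

## Binarization and Boolean gates

A trace becomes a binary signal via a threshold $\theta$:
$I(t) = 1$ if $V(t) \ge \theta$ (inclusive at equality), else 0. Two
conventions exist in the source material — a fixed $\theta = 50$ mV used
for illustrating gate waveforms, and half the channel's mean amplitude used
for the reported gate statistics. Both are implemented
(`threshold_spec("fixed", ...)` / `threshold_spec("half_amplitude", ...)`);
**half-amplitude is the default** for frequency experiments because it is
the convention that reproduces the reported values. The reference amplitude
is the channel's nominal model amplitude, not a running estimate.

The seven gates (AND, OR, NOT, XOR, NAND, NOR, XNOR) apply their truth
tables sample-wise; NOT is unary and, by convention, acts on channel A.
Each result carries its high-state frequency — the fraction of output
samples equal to 1. The usual identities (NAND = ¬AND, inclusion–exclusion
on frequencies, `freq(NOT A) = 1 − freq(A)`) hold exactly and are enforced
by tests.

```{r gates}
round(gate_frequency_experiment(ensemble_preset("pure_algae"),
                                "ChA", "ChB"), 3)
```

For an undamped sinusoid thresholded at half its amplitude, the high
fraction tends to $1/3$ (the arcsine geometry of $\sin x \ge 1/2$); the
deterministic experiment values above are grid-exact and reproducible to
the last bit.

## Noise robustness and correlation

`gate_error_rate()` compares a clean pipeline (generate → binarize → gate)
with a noisy one in which independent Gaussian noise — SD expressed as a
fraction of each channel's nominal amplitude, 10% by default — is added to
the *analog* signal before binarization. Both pipelines share the same
deterministic signal, so the comparison isolates the noise. Noise streams
are seeded per channel and bit-reproducible; replicate averaging is
available via `gate_error_table(..., replicates =)`.

For the unary NOT gate the per-sample flip probability is exactly
$\Phi(-|V(t) - \theta|/\sigma)$, which gives a semi-analytic quadrature
value the Monte Carlo estimate must match within binomial error — this is
the package's internal calibration check. Error at zero noise is exactly 0,
and the error rate is monotone in the noise SD.

The reported error-rate *values* for the recorded systems are **not**
targets: under the stated model (10% noise, half-amplitude thresholds) the
semi-analytic flip rates are near 0.03 per channel, well below the reported
0.10–0.17, so the exact procedure behind those numbers is ambiguous. The
package therefore reports error rates but asserts only their structural
properties. The same applies to the reported pairwise correlation values:
`correlation_matrix()` computes plain Pearson correlation of the analog
model ensemble, and tests assert symmetry, unit diagonal and positive
semidefiniteness rather than specific printed coefficients, several of
which (e.g. near-unity correlation between channels whose phases drift by
more than a cycle over the window) are not consistent with plain Pearson on
the stated model.

## What the generator does and does not emulate

The synthetic module reproduces the *assumed* structure of the recordings:
damped sinusoids with the published per-channel amplitudes and periods,
additive white Gaussian noise scaled to channel amplitude, and optional
linear baseline drift. It does **not** emulate light/dark-cycle forcing,
metabolic pH feedback, electrode physics, amplitude non-stationarity or
non-sinusoidal spike shapes seen in real traces. Passing the recovery tests
therefore demonstrates that the pipeline is correct on data satisfying its
own model assumptions — not that the model captures every feature of live
recordings.

## Problem sizes and runtime

The deterministic gate experiments use the reported protocol directly:
10 000 s at 1 Hz (10 000 samples) and 2.5 Hz (25 000 samples). Parameter
recovery spans periods 200–5000 s at five cycles each; the Monte Carlo /
quadrature comparison uses $10^5$ samples; monotonicity checks average 20
replicates of 10 000 samples per noise level. The full test suite runs in a
few seconds on one core.

## Limitations

* Peak counts for real recordings depend on detrending choices and are
  data-dependent; they are informational in the presets, never recomputed
  targets.
* The zero-phase convention is unverifiable from the published material;
  all deterministic results are conditional on it.
* No spectral estimation is provided: the metrics are time-domain peak
  statistics by design.
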