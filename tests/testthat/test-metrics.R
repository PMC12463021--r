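test_that("cycle periods are consecutive peak spacings", {
  pt <- structure(list(peak_times = c(100, 400, 700), peak_values = c(1, 1, 1),
                       trough_times = numeric(0), trough_values = numeric(0)),
                  class = "peak_table")
  expect_equal(cycle_periods(pt), c(300, 300))
  pt$peak_times <- 100; pt$peak_values <- 1
  expect_length(cycle_periods(pt), 0L)

  # telescoping: periods sum to last minus first peak time
  ts <- make_sine_ts(80, 500, 5000)
  det <- detect_extrema(ts)
  expect_equal(sum(cycle_periods(det)),
               max(det$peak_times) - min(det$peak_times))
  expect_true(all(abs(cycle_periods(det) - 500) <= 2))
})

test_that("cycle amplitudes are peak minus lowest in-span trough", {
  pt <- structure(list(peak_times = c(100, 600), peak_values = c(10, 10),
                       trough_times = 300, trough_values = -20),
                  class = "peak_table")
  expect_equal(cycle_amplitudes(pt), 30)
  # no troughs: empty
  pt$trough_times <- numeric(0); pt$trough_values <- numeric(0)
  expect_length(cycle_amplitudes(pt), 0L)

  # sinusoid: every cycle amplitude is the 2A peak-to-trough swing
  det <- detect_extrema(make_sine_ts(80, 500, 5000))
  amps <- cycle_amplitudes(det)
  expect_length(amps, 9L)
  expect_true(all(abs(amps - 160) / 160 < 0.02))
})

test_that("summary statistics follow the defining identities", {
  s <- summarize_oscillation(rep(299.88, 5), rep(50.41, 5), n_peaks = 6)
  expect_equal(s$frequency_Hz, 1 / 299.88)
  expect_equal(round(s$frequency_Hz, 6), 0.003335)
  expect_equal(s$power_mV2Hz, 50.41^2 / 299.88)
  expect_identical(s$sd_amplitude_mV, 0)

  # population-divisor SD agrees with a direct two-pass evaluation
  set.seed(5)
  amps <- runif(40, 20, 120)
  s <- summarize_oscillation(runif(40, 100, 900), amps, 41)
  direct <- sqrt(mean((amps - mean(amps))^2))
  expect_equal(s$sd_amplitude_mV, direct, tolerance = 1e-9)
  # P = Abar^2 / Tbar holds exactly by construction
  expect_identical(s$power_mV2Hz,
                   s$frequency_Hz * s$mean_amplitude_mV^2)

  expect_error(summarize_oscillation(numeric(0), 1, 1), "at least one")
})

test_that("pipeline recovers known parameters from noiseless channels", {
  cases <- expand.grid(A = c(15, 80, 200), T = c(200, 1000, 5000))
  for (i in seq_len(nrow(cases))) {
    A <- cases$A[i]; T <- cases$T[i]
    ts <- make_sine_ts(A, T, duration = 5 * T)
    res <- analyze_channel(ts, detrend = FALSE)
    tol_T <- max(2, 0.005 * T)
    expect_lt(abs(res$summary$mean_period_s - T), tol_T)
    expect_lt(abs(res$summary$mean_amplitude_mV - 2 * A) / (2 * A), 0.03)
  }
})

test_that("pipeline recovers the period under 10% noise after filtering", {
  ts <- make_sine_ts(80, 500, 5000)
  noisy <- add_gaussian_noise(ts, 0.1, reference_amplitude = 80, seed = 7)
  res <- analyze_channel(noisy, detrend = FALSE, filter_cutoff = 0.01)
  expect_lt(abs(res$summary$mean_period_s - 500) / 500, 0.02)
})

test_that("flat input propagates an error from summarize", {
  flat <- osc_timeseries(rep(0, 1000), rate = 1)
  expect_error(analyze_channel(flat), "at least one")
})

test_that("ensemble summary has the expected table shape", {
  ens <- generate_ensemble(ensemble_preset("pure_algae"), 4000, 1)
  # restrict to fast channels so every one has >= 2 peaks in 4000 s
  tab <- summarize_ensemble(ens[c("ChB", "ChC", "ChF", "ChH")],
                            detrend = FALSE)
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("label", "mean_amplitude_mV", "mean_period_s",
                      "n_peaks", "frequency_Hz", "power_mV2Hz",
                      "sd_amplitude_mV"))
  expect_equal(tab$mean_period_s[tab$label == "ChB"], 299.88,
               tolerance = 0.01)
})
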