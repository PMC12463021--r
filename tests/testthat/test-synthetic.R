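test_that("damped sinusoid evaluates the channel model pointwise", {
  chE <- channel_params("ChE", 80.94, 724.00, alpha_per_s = 1.29e-6)
  expect_identical(damped_sine_value(chE, 0), 0)
  # quarter period: sin = 1, value is the damped envelope
  expect_equal(damped_sine_value(chE, 181.0), 80.94 * exp(-1.29e-6 * 181),
               tolerance = 1e-9)
  expect_equal(damped_sine_value(chE, 181.0), 80.921, tolerance = 1e-4)
  # full period returns to ~0
  chF <- channel_params("ChF", 191.42, 403.78, alpha_per_s = 1e-6)
  expect_lt(abs(damped_sine_value(chF, 403.78)), 1e-6 * 191.42)
  # phase shifts the argument
  expect_equal(damped_sine_value(chE, 0, phase = pi / 2), 80.94,
               tolerance = 1e-9)
})

test_that("envelope bound and undamped periodicity hold across parameters", {
  set.seed(11)
  for (i in 1:20) {
    A <- runif(1, 15, 200); T <- runif(1, 200, 5000)
    alpha <- runif(1, 0, 1e-5)
    p <- channel_params("Z", A, T, alpha)
    t <- seq(0, 10 * T, length.out = 500)
    expect_true(all(abs(damped_sine_value(p, t)) <= A + 1e-12))
    # alpha = 0: exact sinusoid, one-period translation invariance
    p0 <- channel_params("Z", A, T, 0)
    expect_true(all(abs(damped_sine_value(p0, t + T) -
                        damped_sine_value(p0, t)) < 1e-9 * A))
  }
})

test_that("generate_channel samples the half-open grid", {
  p <- channel_params("ChB", 50.41, 299.88)
  ts <- generate_channel(p, 10, 1)
  expect_length(ts, 10L)
  expect_equal(ts_times(ts), 0:9)
  # 2.5 Hz over 10000 s: exactly 25000 samples
  expect_length(generate_channel(p, 10000, 2.5), 25000L)
  # damping keeps the first crest above A * exp(-0.01)
  long <- generate_channel(p, 10000, 1)
  expect_gt(max(long$values), 50.0)
  expect_lte(max(long$values), 50.41)
  # degenerate inputs
  expect_error(generate_channel(p, 0, 1), "duration")
  expect_error(generate_channel(p, 10, -1), "rate")
  zero <- generate_channel(channel_params("Z", 0, 100), 10, 1)
  expect_true(all(zero$values == 0))
})

test_that("ensembles carry one series per preset channel on a common grid", {
  pure <- ensemble_preset("pure_algae")
  ens <- generate_ensemble(pure, duration = 10000, rate = 1)
  expect_named(ens, paste0("Ch", LETTERS[1:8]))
  expect_true(all(vapply(ens, length, 0L) == 10000L))
  mix <- generate_ensemble(ensemble_preset("mixture"), 10000, 2.5)
  expect_true(all(vapply(mix, length, 0L) == 25000L))
  # per-channel parameters flow through: ChB first crest near its amplitude
  expect_equal(max(ens$ChB$values), 50.41, tolerance = 1e-3)
  expect_error(generate_ensemble(pure, duration = 0), "duration")
})

test_that("gaussian noise is seeded, scaled, and leaves caller RNG alone", {
  p <- channel_params("Z", 0, 100)
  zero <- generate_channel(p, 1e5, 1)
  n1 <- add_gaussian_noise(zero, 0.1, reference_amplitude = 50.41, seed = 3)
  n2 <- add_gaussian_noise(zero, 0.1, reference_amplitude = 50.41, seed = 3)
  expect_identical(n1$values, n2$values)
  n3 <- add_gaussian_noise(zero, 0.1, reference_amplitude = 50.41, seed = 4)
  expect_false(identical(n1$values, n3$values))
  # SD = fraction * reference within 2% at n = 1e5
  expect_equal(sd(n1$values), 5.041, tolerance = 0.02)
  # zero fraction is the identity
  expect_identical(add_gaussian_noise(zero, 0, 50.41, seed = 1)$values,
                   zero$values)
  expect_error(add_gaussian_noise(zero, -0.1, 50.41, seed = 1), "sd_fraction")
  # caller's RNG stream is not consumed
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(add_gaussian_noise(zero, 0.1, 50, seed = 5))
  expect_identical(runif(3), before)
})

test_that("linear drift composes with detrending as a round trip", {
  ts <- make_sine_ts(40, 400, 4000)
  drifted <- add_linear_drift(ts, slope = 0.02, intercept = -5)
  expect_equal(drifted$values - ts$values, -5 + 0.02 * ts_times(ts))
  # round trip: detrending the drifted series leaves exactly the residual
  # of the drift-free series, and the fitted slope shifts by the added one
  base_fit <- linear_detrend(ts)
  recovered <- linear_detrend(drifted)
  expect_equal(recovered$slope - base_fit$slope, 0.02, tolerance = 1e-9)
  expect_equal(recovered$residual_series$values,
               base_fit$residual_series$values, tolerance = 1e-9)
  # identity case
  same <- add_linear_drift(ts, 0, 0)
  expect_identical(same$values, ts$values)
})

test_that("presets round-trip through the parameter file format exactly", {
  for (name in c("pure_algae", "mixture")) {
    preset <- ensemble_preset(name)
    f <- withr::local_tempfile(fileext = ".csv")
    write_channel_params(preset, f)
    back <- read_channel_params(f)
    expect_identical(preset_table(back), preset_table(preset))
  }
  expect_error(read_channel_params(
    withr::local_tempfile(lines = "label,amplitude_mV\nChA,1")), "lacks")
})
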