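test_that("binarization is inclusive at the threshold", {
  ts <- osc_timeseries(c(49.9, 50.0, 50.1), rate = 1)
  bs <- binarize(ts, threshold_spec("fixed", theta = 50))
  expect_identical(bs$states, c(0L, 1L, 1L))
  expect_identical(bs$threshold_mV, 50)

  # channel whose amplitude never reaches a 50 mV threshold: all low
  chA <- make_sine_ts(35.94, 929.53, 10000)
  expect_true(all(binarize(chA, threshold_spec("fixed", 50))$states == 0L))

  # half-amplitude threshold on a sinusoid: high one third of the cycle
  fine <- generate_channel(channel_params("ChB", 50.41, 299.88, 0),
                           299.88, 100)
  spec <- threshold_spec("half_amplitude", reference_amplitude = 50.41)
  expect_equal(spec$theta_mV, 25.205)
  expect_equal(mean(binarize(fine, spec)$states), 1 / 3, tolerance = 0.01)

  expect_error(threshold_spec("fixed", theta = -3), "positive")
})

test_that("truth tables enumerate the seven gates correctly", {
  expect_identical(truth_table("NOR")$out, c(1L, 0L, 0L, 0L))
  expect_identical(truth_table("AND")$out, c(0L, 0L, 0L, 1L))
  expect_identical(truth_table("NOT")$out, c(1L, 0L))
  # every table row matches eval_gate on constant inputs
  const_sig <- function(bit, n = 4) {
    binarize(osc_timeseries(rep(if (bit) 9 else 1, n), 1),
             threshold_spec("fixed", 5))
  }
  for (g in c("AND", "OR", "XOR", "NAND", "NOR", "XNOR")) {
    tt <- truth_table(g)
    for (r in seq_len(nrow(tt))) {
      res <- eval_gate(g, const_sig(tt$a[r]), const_sig(tt$b[r]))
      expect_true(all(res$output$states == tt$out[r]))
    }
  }
  tt <- truth_table("NOT")
  for (r in 1:2) {
    expect_true(all(eval_gate("NOT", const_sig(tt$a[r]))$output$states ==
                    tt$out[r]))
  }
})

test_that("gate evaluation validates arity and grids", {
  a <- binarize(osc_timeseries(c(1, 9, 1, 9), 1), threshold_spec("fixed", 5))
  b <- binarize(osc_timeseries(c(9, 9, 1, 1), 1), threshold_spec("fixed", 5))
  short <- binarize(osc_timeseries(c(9, 1), 1), threshold_spec("fixed", 5))
  expect_error(eval_gate("AND", a, short), "grid")
  expect_error(eval_gate("NOT", a, b), "unary")
  expect_error(eval_gate("OR", a), "two")
  expect_identical(eval_gate("AND", a, b)$output$states, c(0L, 1L, 0L, 0L))
  # NOT of all-zero input is all-one with frequency exactly 1
  zero <- binarize(osc_timeseries(rep(0, 50), 1), threshold_spec("fixed", 5))
  res <- eval_gate("NOT", zero)
  expect_identical(res$high_state_frequency, 1)
})

test_that("Boolean identities hold pointwise on random binary inputs", {
  set.seed(31)
  n <- 1e4
  mk <- function() binarize(osc_timeseries(runif(n), 1),
                            threshold_spec("fixed", 0.5))
  a <- mk(); b <- mk()
  out <- function(g) eval_gate(g, a, b)$output$states
  expect_identical(out("NAND"), 1L - out("AND"))
  expect_identical(out("NOR"),  1L - out("OR"))
  expect_identical(out("XNOR"), 1L - out("XOR"))
  expect_identical(out("XOR"),  as.integer(out("OR") & !out("AND")))
  # inclusion-exclusion on high-state frequencies, exact in counts
  expect_identical(sum(out("OR")), sum(a$states) + sum(b$states) -
                   sum(out("AND")))
  # NOT complements the input frequency exactly
  expect_identical(eval_gate("NOT", a)$high_state_frequency,
                   1 - mean(a$states))
})

test_that("gate frequency experiment reproduces the reported values", {
  pure <- gate_frequency_experiment(ensemble_preset("pure_algae"),
                                    "ChA", "ChB")
  expect_equal(unname(pure["AND"]),  0.113, tolerance = 0.005)
  expect_equal(unname(pure["OR"]),   0.564, tolerance = 0.005)
  expect_equal(unname(pure["NOT"]),  0.660, tolerance = 0.005)
  expect_equal(unname(pure["XOR"]),  0.450, tolerance = 0.005)
  expect_equal(unname(pure["NAND"]), 0.887, tolerance = 0.005)
  expect_equal(unname(pure["NOR"]),  0.436, tolerance = 0.005)
  expect_equal(unname(pure["XNOR"]), 0.550, tolerance = 0.005)

  mix <- gate_frequency_experiment(ensemble_preset("mixture"), "ChA", "ChB")
  expect_equal(unname(mix["OR"]),   0.637, tolerance = 0.005)
  expect_equal(unname(mix["NAND"]), 0.883, tolerance = 0.005)

  # determinism: repeated runs are identical
  expect_identical(pure,
    gate_frequency_experiment(ensemble_preset("pure_algae"), "ChA", "ChB"))

  # a threshold above both amplitudes drives every direct gate to 0
  high <- gate_frequency_experiment(ensemble_preset("pure_algae"),
                                    "ChA", "ChB", threshold = 500)
  expect_identical(unname(high[c("AND", "OR", "XOR")]), c(0, 0, 0))
  expect_identical(unname(high[c("NOT", "NAND", "NOR", "XNOR")]),
                   c(1, 1, 1, 1))

  expect_error(gate_frequency_experiment(ensemble_preset("pure_algae"),
                                         "ChZ", "ChB"), "channel")
})
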