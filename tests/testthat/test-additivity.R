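test_that("summed_response integrates with dt weighting over windows", {
  g <- fx_grid()
  expect_equal(summed_response(numeric(g$n_samples), dt = g$dt), 0)

  v <- rep(1, g$n_samples)
  expect_equal(summed_response(v, dt = g$dt), g$n_samples * g$dt)
  ## additive over a disjoint partition of the trial
  w1 <- summed_response(v, dt = g$dt, window = c(0, 0.6))
  w2 <- summed_response(v, dt = g$dt, window = c(0.6, grid_duration(g) - 0.6))
  expect_equal(w1 + w2, summed_response(v, dt = g$dt))
  ## the ECoG-style epoch starting before onset just prepends zeros
  expect_equal(summed_response(v, dt = g$dt, window = c(-0.2, 1.2)),
               summed_response(v, dt = g$dt, window = c(0, 1.0)))
  expect_error(summed_response(v, dt = g$dt, window = c(5, 1)), "outside")
})

test_that("a linear system doubles its sum with duration and ignores ISI", {
  conds <- fx_conditions()
  p <- default_linear_truth(fx_grid())
  p$slow_weights <- setNames(rep(list(numeric(10)), 12), conds$condition_id)
  pred <- predict_linear(conds, p, fx_fast(), fx_slow(), tail = "full")
  sums <- condition_sums(pred, conds)
  s <- setNames(sums$summed_response, sums$condition_id)
  expect_equal(s[["dur320"]], 2 * s[["dur160"]], tolerance = 1e-10)
  isi <- s[grepl("^isi", names(s))]
  expect_equal(unname(isi), rep(s[["dur320"]], 6), tolerance = 1e-10)
})

test_that("the additive prediction is anchored proportionality in on-time", {
  sums <- tibble::tibble(
    condition_id = c("dur160", "dur320", "isi040", "isi640"),
    on_time_s = c(0.16, 0.32, 0.32, 0.32),
    summed_response = c(1.1, 2.4, 2.1, 2.2)
  )
  out <- additive_prediction(sums, anchor = "dur160")
  expect_equal(out$additive_pred[out$condition_id == "dur160"], 1.1)
  expect_equal(out$additive_pred[out$condition_id == "dur320"], 2.2)
  expect_equal(out$additive_pred[grepl("isi", out$condition_id)], c(2.2, 2.2))
  expect_error(additive_prediction(sums, anchor = "nope"), "anchor")
})

test_that("the power-law exponent recovers known scaling laws", {
  x <- c(0.02, 0.04, 0.08, 0.16, 0.32, 0.64)
  expect_equal(subadditivity_exponent(3 * x, x)$c, 1, tolerance = 1e-9)
  expect_equal(subadditivity_exponent(2 * sqrt(x), x)$c, 0.5, tolerance = 1e-6)
  expect_equal(subadditivity_exponent(rep(1.7, 6), x)$c, 0, tolerance = 1e-9)

  ## scale invariance: c unchanged, a absorbs the scale
  base <- subadditivity_exponent(3 * x^0.8, x)
  scaled <- subadditivity_exponent(15 * x^0.8, x)
  expect_equal(scaled$c, base$c, tolerance = 1e-6)
  expect_equal(scaled$a, 5 * base$a, tolerance = 1e-4)

  expect_error(subadditivity_exponent(c(1, -1, 2), c(1, 2, 3)), "nonpositive")
})

test_that("contrast ladder shows saturating sums and a shape transition", {
  truth <- default_dn_truth(fx_grid())
  sim <- simulate_contrast_homogeneity(truth, fx_fast())
  expect_equal(sim$sums$contrast, 2^-(4:0))
  ratios <- sim$sums$summed_response[-1] / sim$sums$summed_response[-5]
  expect_true(all(ratios < 2)) # each contrast doubling less than doubles the sum
  expect_true(all(ratios > 1))
  expect_lt(sim$sums$biphasic_index[1], 0.05) # 6.25%: monophasic
  expect_gt(sim$sums$biphasic_index[5], 0.05) # 100%: biphasic

  ## contrast -> 0 limit: response vanishes
  lo <- simulate_contrast_homogeneity(truth, fx_fast(), contrasts = 1e-6)
  expect_lt(max(abs(lo$curves$response)), 1e-4)
})

test_that("mono- vs biphasic normalization separates sub- from near-additive", {
  truth <- default_dn_truth(fx_grid())
  demo <- demo_mono_vs_biphasic(truth, fx_fast())
  expect_lt(demo$c_mono, demo$c_biphasic)
  expect_lte(demo$c_mono, 0.95) # documented strongly-normalized regime

  ## exponents invariant to global response rescaling
  scaled <- truth
  scaled$numerator_weights <- truth$numerator_weights * 7
  demo2 <- demo_mono_vs_biphasic(scaled, fx_fast())
  expect_equal(demo2$c_mono, demo$c_mono, tolerance = 1e-6)
  expect_equal(demo2$c_biphasic, demo$c_biphasic, tolerance = 1e-6)

  ## zero normalization in both variants: the exactly additive limit
  none <- dn_params(truth$numerator_weights, gamma_diff(0, 2, 0.05, 0, 2, 0.1), 1)
  demo0 <- demo_mono_vs_biphasic(none, fx_fast())
  expect_equal(demo0$c_mono, 1, tolerance = 1e-6)
  expect_equal(demo0$c_biphasic, 1, tolerance = 1e-6)
})

test_that("cross-modality alignment rescales sums without touching the exponent", {
  x <- c(0.02, 0.04, 0.08, 0.16, 0.32, 0.64)
  a <- 2 * x^0.9
  b <- 11 * x^0.9
  al <- align_sums(a, b)
  expect_equal(al$scale, 5.5, tolerance = 1e-10)
  expect_equal(al$aligned, b, tolerance = 1e-10)
  expect_equal(subadditivity_exponent(al$aligned, x)$c,
               subadditivity_exponent(a, x)$c, tolerance = 1e-8)
})
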