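test_that("shared-filter linear fit exactly recovers a noiseless generator", {
  fx <- fx_linear_noiseless()
  fit <- fit_linear(fx$avg, fx_conditions(), fx_fast(), fx_slow(), share_filter = TRUE)
  expect_equal(fit$params$fast_weights, fx$params$fast_weights, tolerance = 1e-6)
  expect_lt(fit$loss, 1e-12)

  ## loss equals the residual sum recomputed from the returned parameters
  pred <- predict_linear(fx_conditions(), fit$params, fx_fast(), fx_slow())
  key <- dplyr::inner_join(pred, fx$avg, by = c("condition_id", "time_s"))
  expect_equal(fit$loss, sum((key$total - key$value)^2), tolerance = 1e-10)
})

test_that("linear least squares satisfies the normal equations", {
  fit <- fit_linear(fx_avg(), fx_conditions(), fx_fast(), fx_slow())
  ## residuals orthogonal to every design column, rebuilt independently
  am <- dplyr::arrange(fx_avg(), condition_id, time_s)
  stim <- render_stimulus(fx_conditions(), fx_grid())
  S <- basis_matrix(fx_slow())
  ## shared-filter normal equations: the shared fast columns are orthogonal
  ## to the residual summed over conditions; slow columns per condition
  fast_acc <- numeric(ncol(basis_matrix(fx_fast())))
  worst_slow <- 0
  for (id in unique(am$condition_id)) {
    y <- am$value[am$condition_id == id]
    res <- y - fit$fitted$total[fit$fitted$condition_id == id]
    s <- stim$s[stim$condition_id == id]
    Xf <- vapply(seq_len(ncol(basis_matrix(fx_fast()))), function(j) {
      convolve_causal(s, basis_matrix(fx_fast())[, j], dt = fx_grid()$dt)
    }, numeric(length(y)))
    fast_acc <- fast_acc + drop(crossprod(Xf, res))
    worst_slow <- max(worst_slow, abs(crossprod(S, res)))
  }
  expect_lt(max(abs(fast_acc)), 1e-6)
  expect_lt(worst_slow, 1e-6)
})

test_that("per-condition linear fits on linear data return identical filters", {
  fx <- fx_linear_noiseless()
  fit <- fit_linear(fx$avg, fx_conditions(), fx_fast(), fx_slow(), share_filter = FALSE)
  filters <- vapply(fx_conditions()$condition_id, function(id) {
    basis_filter(fx_fast(), fit$params$fast_weights[[id]])$values
  }, numeric(fx_grid()$n_samples))
  truth <- basis_filter(fx_fast(), fx$params$fast_weights)$values
  for (j in seq_len(ncol(filters))) {
    expect_equal(filters[, j], truth, tolerance = 1e-6)
  }
})

test_that("DN coordinate descent fits noiseless DN data to high accuracy", {
  grid <- fx_grid()
  truth <- default_dn_truth(grid)
  spec <- generator_spec(noise_sd = 0, slow_amplitude = 0, artifact_amplitude = 0,
                         n_repeats = 1, seven_repeat_conditions = character(0))
  d <- simulate_trials(spec)
  avg <- tibble::tibble(condition_id = d$ground_truth$condition_id,
                        time_s = d$ground_truth$time_s,
                        value = d$ground_truth$fast)
  fit <- fit_dn(avg, fx_conditions(), fx_fast(), fx_slow(), restarts = 2, seed = 0)
  ## compare components (raw parameters are scale-degenerate)
  rel_l2 <- sqrt(sum((fit$fitted$fast - d$ground_truth$fast)^2) /
                   sum(d$ground_truth$fast^2))
  expect_lt(rel_l2, 1e-3)
  expect_true(all(diff(fit$loss_trace) <= 1e-9 * max(1, fit$loss_trace[1])))
})

test_that("DN nests the linear model: on linear data its loss is no worse", {
  fx <- fx_linear_noiseless()
  lin <- fit_linear(fx$avg, fx_conditions(), fx_fast(), fx_slow())
  dn <- fit_dn(fx$avg, fx_conditions(), fx_fast(), fx_slow(), restarts = 1, seed = 0)
  expect_lte(dn$loss, lin$loss + 1e-8)
})

test_that("alternative trend models recover their own generating structure", {
  g <- fx_grid(); tt <- grid_times(g)
  conds <- fx_conditions()[3:6, ]
  ## pure linear ramp, no evoked response
  ramp <- tibble::tibble(
    condition_id = rep(conds$condition_id, each = g$n_samples),
    time_s = rep(tt, nrow(conds)),
    value = rep(0.37 * tt, nrow(conds))
  )
  fit <- fit_alt_model(ramp, conds, kind = "linear_trend")
  expect_true(all(abs(fit$per_condition$c3 - 0.37) < 1e-4)) # slope recovered
  expect_lt(max(abs(fit$fitted$fast)), 1e-3) # no spurious evoked component

  ## flat data: the exponential trend degenerates gracefully
  flat <- dplyr::mutate(ramp, value = 0)
  fit2 <- fit_alt_model(flat, conds, kind = "exponential_trend")
  expect_lt(fit2$loss, 1e-10)
})

test_that("leave-one-condition-out CV scores a noiseless linear system perfectly", {
  fx <- fx_linear_noiseless()
  cv <- crossval_loco(fx$avg, fx_conditions(), fx_fast(), fx_slow(), model = "linear")
  expect_true(all(cv$variance_explained > 1 - 1e-8))
})

test_that("full-curve and fast-only variance explained agree closely", {
  cv_full <- crossval_loco(fx_avg(), fx_conditions(), fx_fast(), fx_slow(),
                           model = "linear", ve_on = "full")
  cv_fast <- crossval_loco(fx_avg(), fx_conditions(), fx_fast(), fx_slow(),
                           model = "linear", ve_on = "fast")
  expect_lt(max(abs(cv_full$variance_explained - cv_fast$variance_explained)), 0.05)
})

test_that("fit results serialize to JSON and reproduce their predictions", {
  fx <- fx_linear_noiseless()
  fit <- fit_linear(fx$avg, fx_conditions(), fx_fast(), fx_slow())
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  params <- params_from_json(path)
  pred1 <- predict_linear(fx_conditions(), fit$params, fx_fast(), fx_slow())
  pred2 <- predict_linear(fx_conditions(), params, fx_fast(), fx_slow())
  expect_equal(pred2$total, pred1$total, tolerance = 1e-12)
})
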