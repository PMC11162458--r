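test_that("causal convolution matches the brute-force double loop", {
  set.seed(7)
  for (rep in 1:5) {
    s <- rnorm(12); f <- rnorm(12); dt <- 0.01
    oracle <- numeric(12)
    for (k in 1:12) {
      for (j in 1:k) oracle[k] <- oracle[k] + s[j] * f[k - j + 1] * dt
    }
    expect_equal(convolve_causal(s, f, dt = dt), oracle, tolerance = 1e-12)
  }
})

test_that("convolution identities: impulse, annihilation, causality", {
  g <- fx_grid()
  f <- gamma_diff_filter(gamma_diff(1, 2, 0.04), g)
  s <- numeric(g$n_samples); s[1] <- 1
  expect_equal(convolve_causal(s, f), f$values * g$dt)
  expect_equal(convolve_causal(numeric(g$n_samples), f), numeric(g$n_samples))

  ## output at sample k ignores stimulus beyond k
  s2 <- s; s2[60:121] <- 5
  expect_equal(convolve_causal(s, f)[1:58], convolve_causal(s2, f)[1:58])
})

test_that("linear prediction decomposes additively into fast and slow parts", {
  fast <- fx_fast(); slow <- fx_slow(); conds <- fx_conditions()[4, ]
  ns <- ncol(basis_matrix(slow))
  v <- list(dur160 = seq_len(ns) / ns)

  p0 <- linear_params(numeric(8), v)
  pr0 <- predict_linear(conds, p0, fast, slow)
  expect_equal(pr0$total, pr0$slow) # zero filter

  u <- c(0.1, 0.4, 0.9, 0.5, 0.2, 0.1, 0, 0)
  p1 <- predict_linear(conds, linear_params(u, v), fast, slow)
  p2 <- predict_linear(conds, linear_params(2 * u, v), fast, slow)
  expect_equal(p2$fast, 2 * p1$fast)

  expect_error(predict_linear(fx_conditions()[1, ], p0, fast, slow), "dur020")
})

test_that("linear fast component is additive over stimulus on-time (full tail)", {
  fast <- fx_fast()
  u <- c(0.1, 0.4, 0.9, 0.5, 0.2, 0.1, 0, 0)
  p <- linear_params(u, list(dur160 = 0, dur320 = 0))
  pr <- predict_linear(
    total_on_time(fx_conditions())[4:5, ],
    linear_params(u, list(dur160 = numeric(10), dur320 = numeric(10))),
    fast, fx_slow(), tail = "full"
  )
  s160 <- sum(pr$fast[pr$condition_id == "dur160"])
  s320 <- sum(pr$fast[pr$condition_id == "dur320"])
  expect_equal(s320, 2 * s160, tolerance = 1e-10)
})

test_that("DN prediction nests the linear model and is safe at zero contrast", {
  fast <- fx_fast(); grid <- fx_grid()
  u <- c(0.1, 0.4, 0.9, 0.5, 0.2, 0.1, 0, 0)
  conds <- fx_conditions()[1:6, ]
  vlist <- setNames(rep(list(numeric(10)), 6), conds$condition_id)

  ## zero denominator weights, sigma = 1: exactly the linear prediction
  dn1 <- dn_params(u, gamma_diff(0, 2, 0.05, 0, 2, 0.1), sigma = 1, vlist)
  pr_dn <- predict_dn(conds, dn1, fast, fx_slow())
  pr_lin <- predict_linear(conds, linear_params(u, vlist), fast, fx_slow())
  expect_equal(pr_dn$fast, pr_lin$fast, tolerance = 1e-12)

  ## general sigma: linear / sigma
  dn2 <- dn_params(u, gamma_diff(0, 2, 0.05, 0, 2, 0.1), sigma = 0.25, vlist)
  expect_equal(predict_dn(conds, dn2, fast)$fast, pr_lin$fast / 0.25,
               tolerance = 1e-12)

  ## zero contrast: identically zero, no division failure
  z <- predict_dn(condition_set(contrast = 0)[1, ],
                  dn_params(u, gamma_diff(1, 2, 0.05), 0.1), fast)
  expect_equal(z$fast, numeric(grid$n_samples))
})

test_that("delayed normalization produces a transient and violates homogeneity", {
  fast <- fx_fast()
  u <- c(0.1, 0.4, 0.9, 0.5, 0.2, 0.1, 0, 0)
  gd <- gamma_diff(1, 2, 0.07) # positive, delayed normalization drive
  cond640 <- fx_conditions()[6, ]

  dn <- predict_dn(cond640, dn_params(u, gd, sigma = 0.05), fast)$fast
  lin <- predict_dn(cond640, dn_params(u, gamma_diff(0, 2, 0.07), sigma = 0.05), fast)$fast
  ## peak-to-steady-state ratio larger, and peak earlier, under normalization
  steady <- function(v) mean(v[55:64])
  expect_gt(max(dn) / steady(dn), max(lin) / steady(lin))
  expect_lte(which.max(dn), which.max(lin))

  ## homogeneity violation: contrast-1 integral < 2 x contrast-0.5 integral
  p <- dn_params(u, gd, sigma = 0.05)
  s1 <- sum(predict_dn(condition_set()[4, ], p, fast, tail = "full")$fast)
  s05 <- sum(predict_dn(condition_set(contrast = 0.5)[4, ], p, fast, tail = "full")$fast)
  expect_lt(s1, 2 * s05)
})

test_that("a nonpositive denominator is rejected, naming the offending time", {
  fast <- fx_fast()
  u <- c(0.1, 0.4, 0.9, 0.5, 0.2, 0.1, 0, 0)
  harsh <- gamma_diff(0.2, 2, 0.02, weight2 = 3, shape2 = 4, scale2 = 0.06)
  expect_error(
    predict_dn(fx_conditions()[6, ], dn_params(u, harsh, sigma = 0.01), fast),
    "nonpositive at t"
  )
})

test_that("equivalent-filter deconvolution recovers a known filter", {
  fast <- fx_fast(); grid <- fx_grid()
  u_true <- c(0.05, 0.3, 0.8, 0.6, 0.25, 0.1, 0.02, 0)
  f_true <- basis_filter(fast, u_true)
  s <- render_stimulus(fx_conditions()[6, ], grid)$s # 640 ms pulse
  curve <- convolve_causal(s, f_true)
  f_hat <- equivalent_filter(curve, s, fast)
  expect_equal(f_hat$values, f_true$values, tolerance = 1e-8)
  expect_false(attr(f_hat, "conditioning_warning"))

  f0 <- equivalent_filter(numeric(grid$n_samples), s, fast)
  expect_equal(f0$values, numeric(grid$n_samples), tolerance = 1e-10)
  expect_error(equivalent_filter(curve, numeric(grid$n_samples), fast), "zero")
})

test_that("per-condition filters from a linear generator share one shape", {
  fast <- fx_fast(); grid <- fx_grid()
  u_true <- c(0.05, 0.3, 0.8, 0.6, 0.25, 0.1, 0.02, 0)
  f_true <- basis_filter(fast, u_true)
  stim <- render_stimulus(fx_conditions(), grid)
  for (id in fx_conditions()$condition_id) {
    s <- stim$s[stim$condition_id == id]
    f_hat <- equivalent_filter(convolve_causal(s, f_true), s, fast)
    expect_equal(f_hat$values, f_true$values, tolerance = 1e-6)
  }
})
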