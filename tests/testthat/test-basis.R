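test_that("fast raised-cosine basis has the documented geometry", {
  g <- fx_grid()
  fb <- fast_basis(g, n_funcs = 8)
  M <- basis_matrix(fb)
  tt <- grid_times(g)

  expect_equal(fb$coverage_s, 0.26) # VSDI default
  expect_equal(fast_basis(gcamp_grid())$coverage_s, 0.32) # GCaMP default
  expect_equal(unname(apply(M, 2, max)), rep(1, 8))
  expect_true(all(M >= 0))
  expect_true(all(M[tt > fb$coverage_s + 1e-9, ] == 0))

  ## log-warped spacing: successive peak-to-peak intervals non-decreasing
  peaks <- tt[apply(M, 2, which.max)]
  expect_true(all(diff(diff(peaks)) >= -1e-9))
  ## well-posed least squares
  expect_equal(qr(M)$rank, ncol(M))
})

test_that("slow basis spans the trial with reversed (slow-to-fast) ordering", {
  g <- fx_grid()
  sb <- slow_basis(g, n_funcs = 10)
  M <- basis_matrix(sb)
  expect_equal(sb$coverage_s, grid_duration(g))
  widths <- apply(M, 2, function(v) sum(v > 1e-6))
  expect_gt(widths[1], widths[ncol(M)]) # first wider/slower than last
  expect_equal(drop(M %*% numeric(10)), numeric(g$n_samples)) # zero weights
})

test_that("difference-of-Gammas filter covers mono- and biphasic regimes", {
  g <- fx_grid()
  mono <- gamma_diff_filter(gamma_diff(1, 2, 0.05, weight2 = 0), g)
  expect_true(all(mono$values >= 0))
  expect_equal(biphasic_index(mono), 0)

  same <- gamma_diff_filter(gamma_diff(1, 3, 0.04, weight2 = 1, shape2 = 3, scale2 = 0.04), g)
  expect_equal(same$values, numeric(g$n_samples))

  bi <- gamma_diff_filter(gamma_diff(1, 2, 0.03, weight2 = 0.5, shape2 = 2, scale2 = 0.09), g)
  v <- bi$values[seq_len(sum(grid_times(g) <= 0.6))]
  sign_changes <- sum(diff(sign(v[abs(v) > 1e-12])) != 0)
  expect_equal(sign_changes, 1L) # crosses zero exactly once after its peak
  expect_gt(biphasic_index(bi), 0)

  expect_error(gamma_diff(1, shape1 = 0.5, scale1 = 0.05), "shape1")
  expect_error(gamma_diff(1, 2, scale1 = -0.1), "scale1")
})

test_that("gamma_diff_filter is linear in the lobe weights", {
  g <- fx_grid()
  f1 <- gamma_diff_filter(gamma_diff(1, 2, 0.03, 0, 4, 0.05), g)$values
  f2 <- gamma_diff_filter(gamma_diff(0, 2, 0.03, 1, 4, 0.05), g)$values
  f12 <- gamma_diff_filter(gamma_diff(2, 2, 0.03, 3, 4, 0.05), g)$values
  expect_equal(f12, 2 * f1 + 3 * f2, tolerance = 1e-12)
})

test_that("time_to_peak reads the grid time of the maximum", {
  g <- fx_grid()
  imp <- numeric(g$n_samples); imp[6] <- 1 # sample index 5, 0-based
  f <- filter_shape(g, imp)
  expect_equal(time_to_peak(f), 0.050)
  expect_equal(time_to_peak(filter_shape(g, 3.7 * imp)), 0.050) # scale invariant

  ## raised cosine centered at 40 ms peaks there
  tt <- grid_times(g)
  rc <- ifelse(abs(tt - 0.04) <= 0.03, (1 + cos(pi * (tt - 0.04) / 0.03)) / 2, 0)
  expect_equal(time_to_peak(filter_shape(g, rc)), 0.040)

  expect_error(time_to_peak(filter_shape(g, numeric(g$n_samples))), "positive")
})

test_that("biphasic_index measures the negative-lobe area fraction", {
  g <- fx_grid()
  tt <- grid_times(g)
  anti <- sin(2 * pi * tt / max(tt)) # equal positive and negative lobes
  expect_equal(biphasic_index(filter_shape(g, anti)), 0.5, tolerance = 1e-10)
  expect_equal(biphasic_index(gamma_diff_filter(gamma_diff(2, 3, 0.05), g)), 0)
  expect_error(biphasic_index(filter_shape(g, numeric(g$n_samples))), "zero")
})

test_that("basis sets and filters export as labelled delimited text", {
  fb <- fast_basis(fx_grid(), 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_basis(fb, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("time_s", colnames(basis_matrix(fb))))
  expect_equal(as.matrix(back[, -1]), basis_matrix(fb), ignore_attr = TRUE)
})
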