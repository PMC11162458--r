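test_that("the canonical DN truth has the documented filter geometry", {
  g <- fx_grid()
  truth <- default_dn_truth(g)
  fl <- basis_filter(fx_fast(), truth$numerator_weights)
  fn <- gamma_diff_filter(truth$denom_gamma, g)
  expect_equal(time_to_peak(fl), 0.050)
  expect_equal(time_to_peak(fn), 0.070) # normalization drive is delayed
  expect_gt(biphasic_index(fn), 0)
  tt <- grid_times(g)
  expect_equal(tt[which.min(fn$values)], 0.150, tolerance = 0.021) # negative lobe
  ## peak evoked response is ~1 response unit across the canonical conditions
  pred <- predict_dn(fx_conditions(), truth, fx_fast())
  expect_equal(max(pred$fast), 1, tolerance = 1e-3)

  expect_error(default_dn_truth(time_grid(0.2, 10)), "coarse")
})

test_that("with all nuisance terms off, trials equal the ground truth exactly", {
  spec <- generator_spec(noise_sd = 0, slow_amplitude = 0, artifact_amplitude = 0)
  d <- simulate_trials(spec)
  merged <- dplyr::inner_join(d$trials, d$ground_truth,
                              by = c("condition_id", "time_s"))
  expect_equal(merged$value, merged$fast, tolerance = 1e-12)
  expect_true(all(d$blanks$value == 0))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  d1 <- simulate_trials(generator_spec(seed = 123L))
  d2 <- simulate_trials(generator_spec(seed = 123L))
  expect_identical(d1, d2)
  d3 <- simulate_trials(generator_spec(seed = 124L))
  expect_false(identical(d1$trials$value, d3$trials$value))
})

test_that("repeat counts follow the experimental yield (8, with 2 conditions at 7)", {
  d <- fx_dataset()
  counts <- d$trials |>
    dplyr::distinct(condition_id, `repeat`) |>
    dplyr::count(condition_id)
  expect_equal(sort(unique(counts$n)), c(7L, 8L))
  expect_equal(sum(counts$n == 7L), 2L)
  expect_equal(sum(counts$n == 8L), 10L)
})

test_that("blank subtraction removes the shared artifact exactly when noiseless", {
  spec <- generator_spec(noise_sd = 0, slow_amplitude = 0, artifact_amplitude = 0.5)
  d <- simulate_trials(spec)
  pp <- preprocess_trials(d$trials, d$blanks, shift_ms = 0)
  merged <- dplyr::inner_join(pp, d$ground_truth, by = c("condition_id", "time_s"))
  ## after artifact removal only the fast component remains, re-zeroed at t=0
  gt0 <- d$ground_truth[d$ground_truth$time_s == 0, c("condition_id", "fast")]
  names(gt0)[2] <- "fast0"
  merged <- dplyr::left_join(merged, gt0, by = "condition_id")
  expect_equal(merged$value, merged$fast - merged$fast0, tolerance = 1e-12)
})

test_that("the per-trial slow trend is an order of magnitude slower than evoked", {
  g <- fx_grid()
  set.seed(99)
  for (i in 1:20) {
    tr <- delaynorm:::random_slow_trend(g, 0.1)
    sp <- Mod(stats::fft(tr))^2
    freq <- (seq_along(tr) - 1) / (length(tr) * g$dt)
    hi <- sum(sp[freq > 4 & freq < (1 / g$dt - 4)])
    expect_lt(hi / sum(sp[-1]), 0.01)
    expect_equal(sqrt(mean(tr^2)), 0.1, tolerance = 1e-9)
  }
})

test_that("the blank mean converges to the shared artifact as repeats grow", {
  g <- fx_grid()
  spec_small <- generator_spec(n_blank_trials = 4L, seed = 7L)
  spec_big <- generator_spec(n_blank_trials = 400L, seed = 7L)
  artifact <- delaynorm:::shared_artifact(g, spec_big$artifact_amplitude)
  err <- function(spec) {
    d <- simulate_trials(spec)
    bm <- d$blanks |>
      dplyr::group_by(time_s) |>
      dplyr::summarise(value = mean(value), .groups = "drop")
    sqrt(mean((bm$value - artifact)^2))
  }
  expect_lt(err(spec_big), err(spec_small) / 3)
})

test_that("a generated dataset round-trips to disk with its provenance sidecar", {
  dir <- withr::local_tempdir()
  spec <- generator_spec(seed = 3L, n_repeats = 2L,
                         seven_repeat_conditions = character(0),
                         n_blank_trials = 2L)
  d <- simulate_trials(spec, fx_conditions()[1:3, ])
  write_dataset(d, spec, dir)
  back <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(back$trials$value, d$trials$value, tolerance = 1e-12)
  side <- jsonlite::fromJSON(file.path(dir, "generator_spec.json"))
  expect_equal(side$seed, 3L)
  expect_equal(side$grid$dt, fx_grid()$dt)
})
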