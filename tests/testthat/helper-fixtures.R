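## shared fixtures, memoized so expensive fits run once per test session
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

fx_grid <- function() vsdi_grid()
fx_fast <- function() memo("fast", fast_basis(fx_grid()))
fx_slow <- function() memo("slow", slow_basis(fx_grid()))
fx_conditions <- function() memo("conds", condition_set())

## canonical DN-generated dataset at the study conditions (10% noise, 8
## repeats, seed 0) and its preprocessed average
fx_dataset <- function() memo("dataset", simulate_trials(generator_spec(seed = 0L)))
fx_avg <- function() memo("avg", {
  d <- fx_dataset()
  average_trials(preprocess_trials(d$trials, d$blanks, shift_ms = 0))
})

## the full DN fit on the canonical dataset (shared across test files)
fx_dn_fit <- function() memo("dn_fit", {
  fit_dn(fx_avg(), fx_conditions(), fx_fast(), fx_slow(), restarts = 5L, seed = 0L)
})

## noiseless linear-generator average (fast + known slow weights, no noise)
fx_linear_noiseless <- function() memo("lin_noiseless", {
  grid <- fx_grid()
  fast <- fx_fast()
  slow <- fx_slow()
  conds <- fx_conditions()
  set.seed(42)
  u <- c(0.2, 0.5, 1.0, 0.8, 0.3, 0.1, 0.05, 0.02)
  v <- lapply(seq_len(nrow(conds)), function(i) rnorm(ncol(basis_matrix(slow)), sd = 0.05))
  names(v) <- conds$condition_id
  params <- linear_params(u, v)
  pred <- predict_linear(conds, params, fast, slow)
  list(
    params = params,
    avg = tibble::tibble(condition_id = pred$condition_id,
                         time_s = pred$time_s, value = pred$total)
  )
})
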