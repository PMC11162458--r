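#' Sampling grids for trial time courses
#'
#' A time grid describes the regular sampling of one imaging trial: the
#' sampling step `dt` (seconds), the number of samples, and the sample index
#' at which the stimulus onset is aligned. Sample `k` (0-based) spans
#' `[k * dt, (k + 1) * dt)`, so sample times are `k * dt`.
#'
#' Two presets match the imaging modalities the package models:
#' `vsdi_grid()` is 100 Hz over a 1.2 s trial (121 samples including t = 0);
#' `gcamp_grid()` is 20 Hz over a 1.35 s trial (28 samples).
#'
#' @param dt Seconds per sample; must be positive.
#' @param n_samples Number of samples; at least 1.
#' @param onset_index 0-based sample index of stimulus onset (default 0,
#'   i.e. responses are assumed already latency-aligned).
#'
#' @return An object of class `time_grid`: a list with fields `dt`,
#'   `n_samples`, `onset_index`.
#' @export
#' @examples
#' g <- vsdi_grid()
#' g$n_samples
#' head(grid_times(g))
time_grid <- function(dt, n_samples, onset_index = 0L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (seconds per sample).")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    abort("`n_samples` must be a positive integer.")
  }
  onset_index <- as.integer(onset_index)
  if (is.na(onset_index) || onset_index < 0L || onset_index >= n_samples) {
    abort("`onset_index` must satisfy 0 <= onset_index < n_samples.")
  }
  structure(
    list(dt = dt, n_samples = n_samples, onset_index = onset_index),
    class = "time_grid"
  )
}

#' @rdname time_grid
#' @export
vsdi_grid <- function(onset_index = 0L) {
  time_grid(dt = 0.010, n_samples = 121L, onset_index = onset_index)
}

#' @rdname time_grid
#' @export
gcamp_grid <- function(onset_index = 0L) {
  time_grid(dt = 0.050, n_samples = 27L, onset_index = onset_index)
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  (seq_len(grid$n_samples) - 1L) * grid$dt
}

#' @rdname time_grid
#' @export
grid_duration <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$dt * grid$n_samples
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> dt = %g s (%g Hz), %d samples, %.3g s trial, onset at sample %d\n",
    x$dt, 1 / x$dt, x$n_samples, grid_duration(x), x$onset_index
  ))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$dt - b$dt) < tol && a$n_samples == b$n_samples
}

## infer a time_grid from a strictly increasing, regularly spaced time column
grid_from_times <- function(time_s, where = "time_s") {
  if (length(time_s) < 1L) abort(sprintf("empty %s vector.", where))
  if (length(time_s) == 1L) return(time_grid(dt = 1, n_samples = 1L))
  steps <- diff(time_s)
  if (any(steps <= 0)) abort(sprintf("%s must be strictly increasing.", where))
  dt <- steps[1]
  if (any(abs(steps - dt) > 1e-9)) {
    abort(sprintf("%s is not regularly sampled (non-constant step).", where))
  }
  time_grid(dt = dt, n_samples = length(time_s))
}
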