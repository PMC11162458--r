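#' Raised-cosine temporal basis sets
#'
#' The fast component of every model is a filter expanded in raised cosines
#' whose time axis is logarithmically warped, so functions near time 0 vary
#' quickly and later ones slow down — matching the observation that evoked
#' dynamics are fastest just after stimulus onset. The slow component uses
#' the mirror construction: raised cosines on reversed warped time spanning
#' the whole trial, wide and slow early, narrow and fast late (trials are
#' aligned and zeroed at onset, so variability accumulates toward trial end).
#'
#' Warp: `phi(t) = log(t + t0)` with `t0 = dt`. Peak centers are equally
#' spaced in warped time; each function is
#' `(1 + cos(pi * clip((phi - c_i) / (2 * delta), -1, 1))) / 2`
#' with `delta` the center spacing, then rescaled to unit sampled maximum.
#' The support of the last fast function ends at `coverage_s`.
#'
#' @param grid A [time_grid()].
#' @param n_funcs Number of basis functions (>= 2).
#' @param coverage_s Temporal support of the longest fast function, seconds.
#'   Defaults: 0.26 s on a 100 Hz VSDI-style grid, 0.32 s on a 20 Hz
#'   GCaMP-style grid.
#' @return A `basis_set`: list with `grid`, `matrix` (n_samples x n_funcs),
#'   `coverage_s`, `kind` ("fast" or "slow").
#' @export
#' @examples
#' fb <- fast_basis(vsdi_grid(), n_funcs = 8)
#' dim(basis_matrix(fb))
fast_basis <- function(grid, n_funcs = 8L,
                       coverage_s = if (grid$dt <= 0.025) 0.26 else 0.32) {
  stopifnot(inherits(grid, "time_grid"))
  n_funcs <- as.integer(n_funcs)
  if (n_funcs < 2L) abort("`n_funcs` must be at least 2.")
  if (coverage_s > grid_duration(grid) + 1e-12) {
    abort("`coverage_s` exceeds the trial duration.")
  }
  t0 <- grid$dt
  tt <- grid_times(grid)
  phi <- log(tt + t0)
  phi_min <- log(t0)
  phi_max <- log(coverage_s + t0)
  delta <- (phi_max - phi_min) / (n_funcs + 2)
  centers <- phi_min + seq_len(n_funcs) * delta
  mat <- raised_cosines(phi, centers, delta)
  mat[tt > coverage_s + 1e-12, ] <- 0 # clip numerical dust past coverage
  new_basis_set(grid, mat, coverage_s, "fast")
}

#' @rdname fast_basis
#' @export
slow_basis <- function(grid, n_funcs = 10L) {
  stopifnot(inherits(grid, "time_grid"))
  n_funcs <- as.integer(n_funcs)
  if (n_funcs < 2L) abort("`n_funcs` must be at least 2.")
  dur <- grid_duration(grid)
  t0 <- grid$dt
  tt <- grid_times(grid)
  ## fast-style construction on reversed time u = T_end - t, so narrow/fast
  ## functions sit at trial end and wide/slow ones at the start
  u <- max(tt) - tt
  phi <- log(u + t0)
  phi_min <- log(t0)
  phi_max <- log(max(tt) + t0)
  delta <- (phi_max - phi_min) / (n_funcs + 2)
  centers <- phi_min + seq_len(n_funcs) * delta
  mat <- raised_cosines(phi, centers, delta)
  mat <- mat[, rev(seq_len(n_funcs)), drop = FALSE] # order slow-to-fast
  new_basis_set(grid, mat, dur, "slow")
}

raised_cosines <- function(phi, centers, delta) {
  mat <- vapply(centers, function(ci) {
    arg <- pmin(pmax((phi - ci) / (2 * delta), -1), 1)
    (1 + cos(pi * arg)) / 2
  }, numeric(length(phi)))
  ## rescale each sampled function to peak exactly at 1
  sweep(mat, 2, apply(mat, 2, max), "/")
}

new_basis_set <- function(grid, mat, coverage_s, kind) {
  colnames(mat) <- sprintf("%s%02d", substr(kind, 1, 1), seq_len(ncol(mat)))
  structure(
    list(grid = grid, matrix = mat, coverage_s = coverage_s, kind = kind),
    class = "basis_set"
  )
}

#' @rdname fast_basis
#' @param basis A `basis_set`.
#' @export
basis_matrix <- function(basis) {
  stopifnot(inherits(basis, "basis_set"))
  basis$matrix
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf(
    "<basis_set> %s: %d raised cosines on %g Hz grid, coverage %.3g s\n",
    x$kind, ncol(x$matrix), 1 / x$grid$dt, x$coverage_s
  ))
  invisible(x)
}

#' @export
as.data.frame.basis_set <- function(x, ...) {
  as.data.frame(tidy.basis_set(x))
}

#' Tidy a basis set into long format
#'
#' @param x A `basis_set`.
#' @param ... Unused.
#' @return Tibble `basis_fn, time_s, value`.
#' @export
tidy.basis_set <- function(x, ...) {
  tibble::tibble(
    basis_fn = rep(colnames(x$matrix), each = x$grid$n_samples),
    time_s = rep(grid_times(x$grid), ncol(x$matrix)),
    value = as.vector(x$matrix)
  )
}

#' Export a basis set or filter as delimited text
#'
#' One column per function (header row of labels), one row per time sample,
#' first column `time_s`.
#'
#' @param x A `basis_set` or `filter_shape`.
#' @param path Output path.
#' @export
write_basis <- function(x, path) {
  if (inherits(x, "filter_shape")) {
    df <- tibble::tibble(time_s = grid_times(x$grid), filter = x$values)
  } else {
    stopifnot(inherits(x, "basis_set"))
    df <- tibble::as_tibble(cbind(time_s = grid_times(x$grid), x$matrix))
  }
  readr::write_tsv(df, path)
  invisible(path)
}

## ---- filters ---------------------------------------------------------------

#' Sampled impulse-response filters
#'
#' `filter_shape()` wraps a sampled impulse response on a grid.
#' `basis_filter()` forms the weighted sum of basis functions (the filter
#' `f(t) = sum_i u_i f_i(t)`).
#'
#' @param grid A [time_grid()].
#' @param values Sampled filter values (length `n_samples`).
#' @return A `filter_shape` object.
#' @export
filter_shape <- function(grid, values) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_samples) {
    abort("filter length must equal grid$n_samples.")
  }
  if (any(!is.finite(values))) abort("filter values must be finite.")
  structure(list(grid = grid, values = values), class = "filter_shape")
}

#' @rdname filter_shape
#' @param basis A fast `basis_set`.
#' @param weights Numeric weights, one per basis function.
#' @export
basis_filter <- function(basis, weights) {
  stopifnot(inherits(basis, "basis_set"))
  if (length(weights) != ncol(basis$matrix)) {
    abort(sprintf(
      "need %d weights for this basis, got %d.", ncol(basis$matrix), length(weights)
    ))
  }
  filter_shape(basis$grid, drop(basis$matrix %*% weights))
}

#' @export
print.filter_shape <- function(x, ...) {
  cat(sprintf(
    "<filter_shape> %d samples at %g Hz; peak %.4g at %.3g s\n",
    x$grid$n_samples, 1 / x$grid$dt, max(x$values),
    grid_times(x$grid)[which.max(x$values)]
  ))
  invisible(x)
}

#' Difference-of-Gammas normalization filter
#'
#' The delayed-normalization denominator filter `f_n(t)` is parameterized as
#' a difference of two Gamma-shaped kernels, each normalized to unit peak
#' before weighting so the weights read as amplitudes:
#' `f_n(t) = w1 * gamma(t; k1, s1) - w2 * gamma(t; k2, s2)`.
#' With `weight2 = 0` the filter is monophasic (low-pass); with a delayed,
#' positive second component it acquires a negative lobe (biphasic,
#' band-pass), which truncates normalization's suppressive effect in time.
#'
#' @param weight1,weight2 Nonnegative lobe amplitudes.
#' @param shape1,shape2 Gamma shape parameters (> 1, so the kernel peaks at
#'   `(shape - 1) * scale` rather than at 0).
#' @param scale1,scale2 Gamma time scales in seconds (> 0).
#' @return A `gamma_diff` parameter object.
#' @export
#' @examples
#' p <- gamma_diff(weight1 = 1, shape1 = 2, scale1 = 0.07,
#'                 weight2 = 0.6, shape2 = 2, scale2 = 0.15)
#' f <- gamma_diff_filter(p, vsdi_grid())
#' biphasic_index(f) > 0
gamma_diff <- function(weight1, shape1, scale1,
                       weight2 = 0, shape2 = 2, scale2 = 0.1) {
  for (nm in c("shape1", "shape2")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 1) abort(sprintf("`%s` must be > 1.", nm))
  }
  for (nm in c("scale1", "scale2")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) abort(sprintf("`%s` must be positive.", nm))
  }
  for (nm in c("weight1", "weight2")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0) abort(sprintf("`%s` must be nonnegative.", nm))
  }
  structure(
    list(weight1 = weight1, shape1 = shape1, scale1 = scale1,
         weight2 = weight2, shape2 = shape2, scale2 = scale2),
    class = "gamma_diff"
  )
}

## unit-peak Gamma kernel evaluated at times tt (mode at (shape-1)*scale)
gamma_kernel <- function(tt, shape, scale) {
  mode <- (shape - 1) * scale
  peak <- dgamma(mode, shape = shape, scale = scale)
  dgamma(tt, shape = shape, scale = scale) / peak
}

#' @rdname gamma_diff
#' @param p A `gamma_diff` parameter object.
#' @param grid A [time_grid()].
#' @export
gamma_diff_filter <- function(p, grid) {
  stopifnot(inherits(p, "gamma_diff"), inherits(grid, "time_grid"))
  tt <- grid_times(grid)
  v <- p$weight1 * gamma_kernel(tt, p$shape1, p$scale1) -
    p$weight2 * gamma_kernel(tt, p$shape2, p$scale2)
  filter_shape(grid, v)
}

#' Filter-shape summaries
#'
#' `time_to_peak()` returns the grid time of the global maximum (earliest
#' sample on ties). `biphasic_index()` measures how biphasic a curve is:
#' `|negative area| / (|negative area| + positive area)`, 0 for a
#' nonnegative (monophasic) filter, 0.5 for a perfectly antisymmetric one.
#'
#' @param f A `filter_shape`, or a bare numeric curve.
#' @return Seconds (`time_to_peak`) or a ratio in `[0, 1]` (`biphasic_index`).
#' @export
time_to_peak <- function(f) {
  v <- filter_values(f)
  if (all(v <= 0)) abort("filter has no strictly positive value; peak undefined.")
  dt <- if (inherits(f, "filter_shape")) f$grid$dt else {
    abort("time_to_peak() needs a filter_shape (to know dt).")
  }
  (which.max(v) - 1L) * dt
}

#' @rdname time_to_peak
#' @export
biphasic_index <- function(f) {
  v <- filter_values(f)
  pos <- sum(v[v > 0])
  neg <- -sum(v[v < 0])
  if (pos + neg == 0) abort("filter is identically zero; biphasic index undefined.")
  neg / (neg + pos)
}

filter_values <- function(f) {
  if (inherits(f, "filter_shape")) f$values else as.numeric(f)
}
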