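#' Causal discrete convolution of a stimulus with a filter
#'
#' Computes `dt * sum_j s[j] f[k - j]` — the Riemann-sum discretization of
#' `(s * f)(t)` — with zero-padded history before trial start. By default
#' the result is truncated to the trial window (`tail = "truncate"`);
#' `tail = "full"` keeps the entire convolution tail (length
#' `length(s) + length(f) - 1`), which the additivity theory checks need so
#' that response mass falling past trial end is not lost.
#'
#' @param s Numeric stimulus vector, or a tibble from [render_stimulus()]
#'   restricted to one condition.
#' @param f A `filter_shape` or numeric filter vector on the same grid.
#' @param dt Sampling step in seconds (taken from `f` when it is a
#'   `filter_shape`).
#' @param tail `"truncate"` (trial window) or `"full"` (untruncated).
#' @return Numeric vector.
#' @export
#' @examples
#' g <- vsdi_grid()
#' f <- gamma_diff_filter(gamma_diff(1, 2, 0.02), g)
#' s <- numeric(g$n_samples); s[1] <- 1
#' all.equal(convolve_causal(s, f), f$values * g$dt)
convolve_causal <- function(s, f, dt = NULL, tail = c("truncate", "full")) {
  tail <- match.arg(tail)
  if (is.data.frame(s)) {
    if (!"s" %in% names(s)) abort("stimulus tibble must have an `s` column.")
    if ("condition_id" %in% names(s) && length(unique(s$condition_id)) > 1L) {
      abort("pass one condition's stimulus at a time to convolve_causal().")
    }
    s <- s$s
  }
  fv <- filter_values(f)
  if (inherits(f, "filter_shape")) {
    if (is.null(dt)) dt <- f$grid$dt
    if (abs(dt - f$grid$dt) > 1e-12) abort("grid mismatch: `dt` disagrees with the filter's grid.")
  }
  if (is.null(dt)) abort("`dt` must be supplied when `f` is a bare numeric vector.")
  n <- length(s)
  full <- conv_full(s, fv) * dt
  if (tail == "full") full else full[seq_len(n)]
}

## plain full linear convolution (length n + m - 1); FFT-free, n is small
conv_full <- function(x, y) {
  n <- length(x); m <- length(y)
  out <- numeric(n + m - 1L)
  for (j in seq_len(m)) {
    idx <- j:(j + n - 1L)
    out[idx] <- out[idx] + y[j] * x
  }
  out
}

#' Linear model parameter bundle
#'
#' The two-component linear model predicts a trial time course as
#' `r_l(t) = s(t) * f(t) + g(t)` with the filter `f` a weighted sum of fast
#' raised-cosine basis functions (weights `u_i`, shared or per condition)
#' and the slow trend `g` a weighted sum of slow basis functions (weights
#' `v_j`, always per condition).
#'
#' @param fast_weights Numeric vector `u` (shared filter), or a named list
#'   of such vectors keyed by `condition_id` (per-condition filters).
#' @param slow_weights Named list of numeric vectors `v`, keyed by
#'   `condition_id`.
#' @return A `linear_params` object.
#' @export
linear_params <- function(fast_weights, slow_weights) {
  structure(
    list(fast_weights = fast_weights, slow_weights = slow_weights),
    class = "linear_params"
  )
}

#' Delayed-normalization parameter bundle
#'
#' The delayed normalization (DN) model predicts the fast stimulus-evoked
#' component as `(s * f_l) / (sigma + s * f_n)`: a numerator drive through
#' filter `f_l` (expanded in the fast basis), divisively normalized by a
#' delayed drive through `f_n` (a difference of Gammas) plus a positive
#' constant `sigma` that keeps the computation defined at zero contrast.
#' A slow trend `g(t)` is added per condition exactly as in the linear model.
#'
#' @param numerator_weights Fast-basis weights building `f_l`.
#' @param denom_gamma A [gamma_diff()] parameterizing `f_n`.
#' @param sigma Positive semisaturation constant (response units).
#' @param slow_weights Named list of per-condition slow-basis weights (may be
#'   empty for pure fast-component simulation).
#' @return A `dn_params` object.
#' @export
dn_params <- function(numerator_weights, denom_gamma, sigma, slow_weights = list()) {
  stopifnot(inherits(denom_gamma, "gamma_diff"))
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  structure(
    list(numerator_weights = as.numeric(numerator_weights),
         denom_gamma = denom_gamma, sigma = sigma,
         slow_weights = slow_weights),
    class = "dn_params"
  )
}

slow_component_for <- function(id, params, slow) {
  v <- params$slow_weights[[id]]
  if (is.null(v)) {
    ## an empty mapping means "no slow component anywhere"; a non-empty
    ## mapping lacking this condition is a caller error
    if (length(params$slow_weights) > 0L) {
      abort(sprintf("no slow-component weights for condition '%s'.", id))
    }
    return(numeric(slow$grid$n_samples))
  }
  drop(basis_matrix(slow) %*% v)
}

fast_weights_for <- function(id, params) {
  u <- params$fast_weights
  if (is.list(u)) {
    if (is.null(u[[id]])) abort(sprintf("no fast weights for condition '%s'.", id))
    u[[id]]
  } else {
    u
  }
}

#' Forward prediction of the two-component linear model
#'
#' @param conditions Conditions tibble (see [condition_set()]).
#' @param params A [linear_params()] object.
#' @param fast,slow Fast and slow [fast_basis()] sets on the same grid.
#' @param grid Optional grid override (defaults to the fast basis grid).
#' @param tail Convolution tail handling, see [convolve_causal()]. With
#'   `"full"` the returned tibble is longer than the trial.
#' @param fractional Passed to [render_stimulus()].
#' @return Tibble `condition_id, time_s, fast, slow, total`.
#' @export
predict_linear <- function(conditions, params, fast, slow = NULL, grid = fast$grid,
                           tail = c("truncate", "full"), fractional = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(params, "linear_params"), inherits(fast, "basis_set"))
  conditions <- validate_conditions(conditions)
  stim <- render_stimulus(conditions, grid, fractional = fractional)
  out <- lapply(conditions$condition_id, function(id) {
    u <- fast_weights_for(id, params)
    fl <- basis_filter(fast, u)
    s <- stim$s[stim$condition_id == id]
    fc <- convolve_causal(s, fl, tail = tail)
    sc <- if (is.null(slow)) numeric(grid$n_samples) else slow_component_for(id, params, slow)
    length(sc) <- length(fc) # zero-extend slow part under tail = "full"
    sc[is.na(sc)] <- 0
    tibble::tibble(
      condition_id = id,
      time_s = (seq_along(fc) - 1L) * grid$dt,
      fast = fc, slow = sc, total = fc + sc
    )
  })
  dplyr::bind_rows(out)
}

#' Forward prediction of the delayed normalization model
#'
#' Divides the numerator drive `s * f_l` pointwise by `sigma + s * f_n`,
#' then adds the per-condition slow component. The denominator must stay
#' strictly positive; a strongly biphasic `f_n` can drive it negative, which
#' is rejected (not clipped — clipping would silently change model class).
#'
#' @inheritParams predict_linear
#' @param params A [dn_params()] object.
#' @return Tibble `condition_id, time_s, fast, slow, total`.
#' @export
predict_dn <- function(conditions, params, fast, slow = NULL, grid = fast$grid,
                       tail = c("truncate", "full"), fractional = FALSE) {
  tail <- match.arg(tail)
  stopifnot(inherits(params, "dn_params"), inherits(fast, "basis_set"))
  conditions <- validate_conditions(conditions)
  stim <- render_stimulus(conditions, grid, fractional = fractional)
  fl <- basis_filter(fast, params$numerator_weights)
  fn <- gamma_diff_filter(params$denom_gamma, grid)
  out <- lapply(conditions$condition_id, function(id) {
    s <- stim$s[stim$condition_id == id]
    num <- convolve_causal(s, fl, tail = tail)
    den <- params$sigma + convolve_causal(s, fn, tail = tail)
    if (any(den <= 0)) {
      k <- which(den <= 0)[1]
      abort(sprintf(
        "condition '%s': denominator sigma + s*f_n is nonpositive at t = %.3f s; the biphasic normalization filter is too strong for this sigma.",
        id, (k - 1) * grid$dt
      ))
    }
    fc <- num / den
    sc <- if (is.null(slow)) numeric(length(fc)) else slow_component_for(id, params, slow)
    length(sc) <- length(fc)
    sc[is.na(sc)] <- 0
    tibble::tibble(
      condition_id = id,
      time_s = (seq_along(fc) - 1L) * grid$dt,
      fast = fc, slow = sc, total = fc + sc
    )
  })
  dplyr::bind_rows(out)
}

#' Per-condition equivalent linear filter (deconvolution diagnostic)
#'
#' Finds, for one condition, the single linear filter (within the fast basis
#' span) whose convolution with the stimulus best fits the given fast
#' component, by least squares. If the underlying system were linear these
#' per-condition filters would share one shape across all conditions; shape
#' differences (e.g. higher gain and slower peak for brief stimuli) diagnose
#' nonlinearity.
#'
#' Very short pulses poorly constrain the late basis functions; a
#' rank-deficient design is solved by the minimum-norm pseudoinverse and the
#' result carries a `conditioning_warning` flag (an optional ridge penalty
#' `lambda` regularizes that pathology).
#'
#' @param fast_component Numeric curve (one condition's stimulus-evoked
#'   component on the grid).
#' @param s Stimulus vector or one-condition tibble from [render_stimulus()].
#' @param fast Fast `basis_set`.
#' @param lambda Optional ridge penalty (default 0: plain least squares).
#' @return A `filter_shape` with attributes `weights`, `gain` (peak value),
#'   and `conditioning_warning` (logical).
#' @export
equivalent_filter <- function(fast_component, s, fast, lambda = 0) {
  stopifnot(inherits(fast, "basis_set"))
  if (is.data.frame(s)) s <- s$s
  if (all(s == 0)) abort("stimulus is identically zero; deconvolution undefined.")
  y <- as.numeric(fast_component)
  grid <- fast$grid
  if (length(y) != grid$n_samples) abort("curve length must match the basis grid.")
  X <- apply(basis_matrix(fast), 2, function(fi) {
    convolve_causal(s, fi, dt = grid$dt)
  })
  sol <- lstsq_minnorm(X, y, lambda = lambda)
  f <- basis_filter(fast, sol$coef)
  attr(f, "weights") <- sol$coef
  attr(f, "gain") <- max(abs(f$values))
  attr(f, "conditioning_warning") <- sol$rank_deficient
  f
}

## minimum-norm least squares via SVD, with optional ridge; flags deficiency
lstsq_minnorm <- function(X, y, lambda = 0, rtol = 1e-8) {
  if (lambda > 0) {
    p <- ncol(X)
    Xa <- rbind(X, sqrt(lambda) * diag(p))
    ya <- c(y, numeric(p))
    return(lstsq_minnorm(Xa, ya, lambda = 0, rtol = rtol))
  }
  sv <- svd(X)
  keep <- sv$d > rtol * max(sv$d)
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  list(coef = drop(coef), rank_deficient = !all(keep))
}
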