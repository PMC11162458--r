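#' Tidy and glance methods for fitted models
#'
#' broom-style accessors. For a `linear_fit`, [tidy()] returns one row per
#' estimated weight; for a `dn_fit` it returns the interpretable DN
#' quantities: numerator filter time-to-peak and biphasic index, the same
#' for the denominator filter, `sigma`, and the scale-invariant
#' normalization strength (peak denominator drive over `sigma` for the
#' 640 ms condition). [glance()] returns one-row fit summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  u <- x$params$fast_weights
  rows <- list()
  if (is.list(u)) {
    for (id in names(u)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition_id = id, component = "fast",
        term = colnames(basis_matrix(x$fast)), estimate = u[[id]]
      )
    }
  } else {
    rows[[1L]] <- tibble::tibble(
      condition_id = NA_character_, component = "fast",
      term = colnames(basis_matrix(x$fast)), estimate = u
    )
  }
  for (id in names(x$params$slow_weights)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      condition_id = id, component = "slow",
      term = colnames(basis_matrix(x$slow)),
      estimate = x$params$slow_weights[[id]]
    )
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidiers
#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(
    model = "linear", shared_filter = isTRUE(x$share_filter),
    n_conditions = nrow(x$conditions), loss = x$loss,
    converged = isTRUE(x$converged),
    n_warnings = length(x$conditioning_warnings)
  )
}

#' @rdname tidiers
#' @method tidy dn_fit
#' @export
tidy.dn_fit <- function(x, ...) {
  p <- x$params
  grid <- x$grid
  fl <- basis_filter(x$fast, p$numerator_weights)
  fn <- gamma_diff_filter(p$denom_gamma, grid)
  ## invariant normalization strength: peak denominator drive / sigma for
  ## the longest-duration condition present
  long_id <- x$conditions$condition_id[
    which.max(vapply(x$conditions$pulse_durations_ms, max, numeric(1)))
  ]
  s <- render_stimulus(x$conditions[x$conditions$condition_id == long_id, ], grid,
                       fractional = needs_fractional(x$conditions, grid))
  dmax <- max(convolve_causal(s$s, fn))
  tibble::tibble(
    term = c("numerator_time_to_peak_s", "numerator_biphasic_index",
             "denominator_time_to_peak_s", "denominator_biphasic_index",
             "sigma", "normalization_strength"),
    estimate = c(time_to_peak(fl), biphasic_index(fl),
                 time_to_peak(fn), biphasic_index(fn),
                 p$sigma, dmax / p$sigma)
  )
}

#' @rdname tidiers
#' @method glance dn_fit
#' @export
glance.dn_fit <- function(x, ...) {
  tibble::tibble(
    model = "dn", n_conditions = nrow(x$conditions), loss = x$loss,
    n_iterations = x$n_iterations, converged = isTRUE(x$converged),
    n_warnings = length(x$conditioning_warnings)
  )
}

#' @rdname tidiers
#' @method tidy alt_fit
#' @export
tidy.alt_fit <- function(x, ...) {
  tidyr::pivot_longer(x$per_condition, -"condition_id",
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidiers
#' @method glance alt_fit
#' @export
glance.alt_fit <- function(x, ...) {
  tibble::tibble(
    model = x$kind, shared_filter = isTRUE(x$share_filter),
    n_conditions = nrow(x$conditions), loss = x$loss,
    converged = isTRUE(x$converged)
  )
}

#' @rdname tidiers
#' @method tidy additivity_result
#' @export
tidy.additivity_result <- function(x, ...) {
  x$table
}

#' @rdname tidiers
#' @method glance additivity_result
#' @export
glance.additivity_result <- function(x, ...) {
  tibble::tibble(a = x$a, c = x$c, fit_sse = x$fit_sse)
}
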