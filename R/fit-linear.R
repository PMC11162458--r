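## wide response matrix (n_samples x n_conditions) from a tidy averaged table
avg_matrix <- function(avg) {
  need <- c("condition_id", "time_s", "value")
  miss <- setdiff(need, names(avg))
  if (length(miss)) abort(paste0("averaged curves missing column(s): ", toString(miss)))
  wide <- tidyr::pivot_wider(
    avg, id_cols = "time_s",
    names_from = "condition_id", values_from = "value"
  ) |>
    dplyr::arrange(.data$time_s)
  grid <- grid_from_times(wide$time_s)
  Y <- as.matrix(wide[, -1, drop = FALSE])
  if (any(is.na(Y))) abort("averaged curves are ragged across conditions.")
  list(Y = Y, grid = grid, ids = colnames(Y))
}

## per-condition numerator design: columns are conv(s_c, f_i)
fast_design <- function(s, fast) {
  apply(basis_matrix(fast), 2, function(fi) {
    convolve_causal(s, fi, dt = fast$grid$dt)
  })
}

#' Fit the two-component linear model
#'
#' Solves `r(t) = s(t) * f(t) + g(t)` by closed-form least squares, with the
#' filter expanded in the fast basis and the slow trend in the slow basis.
#' With `share_filter = TRUE` (the model-comparison configuration) a single
#' filter-weight vector `u` is fit jointly across all conditions while each
#' condition keeps its own slow weights `v`, via one stacked solve. With
#' `share_filter = FALSE` every condition gets its own filter — the
#' per-condition diagnostic mode in which a linear system must yield
#' identical filters across conditions.
#'
#' Rank-deficient designs are solved by the minimum-norm pseudoinverse and
#' flagged in `conditioning_warnings`, mirroring plain (unregularized)
#' least squares.
#'
#' @param avg Tidy averaged curves (`condition_id, time_s, value`), e.g.
#'   from [average_trials()].
#' @param conditions Conditions tibble covering every `condition_id` in `avg`.
#' @param fast,slow Basis sets from [fast_basis()] / [slow_basis()].
#' @param share_filter Single shared filter (TRUE) or one per condition.
#' @param fractional Passed to [render_stimulus()].
#' @return A `linear_fit` object with elements `params`
#'   ([linear_params()]), `fitted` (tidy tibble), `loss`, `converged`,
#'   `conditioning_warnings`, and the bases used.
#' @export
fit_linear <- function(avg, conditions, fast, slow, share_filter = TRUE,
                       fractional = FALSE) {
  stopifnot(inherits(fast, "basis_set"), inherits(slow, "basis_set"))
  conditions <- validate_conditions(conditions)
  am <- avg_matrix(avg)
  ids <- am$ids
  missing_conds <- setdiff(ids, conditions$condition_id)
  if (length(missing_conds)) {
    abort(paste0("no stimulus definition for condition(s): ", toString(missing_conds)))
  }
  grid <- am$grid
  stim <- render_stimulus(
    conditions[match(ids, conditions$condition_id), ], grid, fractional = fractional
  )
  S <- basis_matrix(slow)
  n <- grid$n_samples
  nf <- ncol(basis_matrix(fast))
  ns <- ncol(S)
  Xf <- lapply(ids, function(id) fast_design(stim$s[stim$condition_id == id], fast))
  names(Xf) <- ids

  warnings <- character(0)
  if (share_filter) {
    C <- length(ids)
    X <- matrix(0, n * C, nf + ns * C)
    y <- numeric(n * C)
    for (i in seq_len(C)) {
      rows <- (i - 1L) * n + seq_len(n)
      X[rows, seq_len(nf)] <- Xf[[i]]
      X[rows, nf + (i - 1L) * ns + seq_len(ns)] <- S
      y[rows] <- am$Y[, i]
    }
    sol <- lstsq_minnorm(X, y)
    if (sol$rank_deficient) warnings <- "shared design is rank deficient; minimum-norm solution returned"
    u <- sol$coef[seq_len(nf)]
    v <- lapply(seq_len(C), function(i) sol$coef[nf + (i - 1L) * ns + seq_len(ns)])
    names(v) <- ids
    params <- linear_params(fast_weights = u, slow_weights = v)
  } else {
    u <- list(); v <- list()
    for (id in ids) {
      sol <- lstsq_minnorm(cbind(Xf[[id]], S), am$Y[, id])
      if (sol$rank_deficient) {
        warnings <- c(warnings, sprintf("condition '%s': design rank deficient", id))
      }
      u[[id]] <- sol$coef[seq_len(nf)]
      v[[id]] <- sol$coef[nf + seq_len(ns)]
    }
    params <- linear_params(fast_weights = u, slow_weights = v)
  }

  fitted <- linear_fitted(params, ids, Xf, S, grid)
  loss <- fit_loss(fitted, am)
  structure(
    list(params = params, fitted = fitted, loss = loss,
         converged = TRUE, n_iterations = 1L,
         conditioning_warnings = warnings,
         fast = fast, slow = slow, grid = grid,
         conditions = conditions[match(ids, conditions$condition_id), ],
         model = "linear", share_filter = share_filter),
    class = c("linear_fit", "dn_model_fit")
  )
}

linear_fitted <- function(params, ids, Xf, S, grid) {
  dplyr::bind_rows(lapply(ids, function(id) {
    u <- fast_weights_for(id, params)
    fc <- drop(Xf[[id]] %*% u)
    sc <- drop(S %*% params$slow_weights[[id]])
    tibble::tibble(condition_id = id, time_s = grid_times(grid),
                   fast = fc, slow = sc, total = fc + sc)
  }))
}

## fitted rows are condition-major in am$ids order, time-ordered within
fit_loss <- function(fitted, am) {
  sum((fitted$total - as.vector(am$Y))^2)
}
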