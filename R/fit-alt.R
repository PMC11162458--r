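#' Alternative trend-extraction models
#'
#' Two simpler decompositions commonly used to split imaging trials into a
#' stimulus-evoked part and a trend, used here to check that additivity
#' conclusions do not hinge on the flexible two-component extraction:
#'
#' * `linear_trend`: `c1 * (s * f_tau)(t) + c3 * t` — a gain-scaled
#'   Gamma-shaped filter (unit peak, shape 2, time constant `tau`) convolved
#'   with the stimulus, plus a linear-in-time drift.
#' * `exponential_trend`: `c1 * (s * f_tau)(t) + c2 * exp(-c3 * t) + c4` —
#'   the same evoked term plus an exponential (typically decaying) trend
#'   with offset.
#'
#' By default a separate filter is fit per condition; `share_filter = TRUE`
#' profiles one shared time constant across conditions. The nonlinear
#' parameters (`tau`, and `c3` for the exponential) are found by simplex
#' search with the linearly entering parameters profiled out in closed form.
#'
#' @inheritParams fit_linear
#' @param kind `"linear_trend"` or `"exponential_trend"`.
#' @param share_filter Share one filter time constant across conditions.
#' @return An `alt_fit` object with `per_condition` (tibble of parameters),
#'   `fitted` (tidy components), `loss`, `kind`, `share_filter`,
#'   `converged`.
#' @export
fit_alt_model <- function(avg, conditions,
                          kind = c("linear_trend", "exponential_trend"),
                          share_filter = FALSE, fractional = FALSE) {
  kind <- match.arg(kind)
  conditions <- validate_conditions(conditions)
  am <- avg_matrix(avg)
  ids <- am$ids
  grid <- am$grid
  tt <- grid_times(grid)
  stim <- render_stimulus(
    conditions[match(ids, conditions$condition_id), ], grid, fractional = fractional
  )
  svecs <- lapply(ids, function(id) stim$s[stim$condition_id == id])
  names(svecs) <- ids

  evoked_col <- function(s, tau) {
    f <- gamma_kernel(tt, shape = 2, scale = tau)
    convolve_causal(s, f, dt = grid$dt)
  }
  ## closed-form solve of the linearly entering parameters given tau (and c3)
  cond_solve <- function(id, tau, log_c3 = NULL) {
    y <- am$Y[, match(id, ids)]
    ev <- evoked_col(svecs[[id]], tau)
    if (kind == "linear_trend") {
      X <- cbind(ev, tt)
      sol <- lstsq_minnorm(X, y)
      pred <- drop(X %*% sol$coef)
      list(coef = c(c1 = sol$coef[1], tau = tau, c3 = sol$coef[2], c4 = NA_real_),
           sse = sum((y - pred)^2), evoked = sol$coef[1] * ev,
           trend = sol$coef[2] * tt)
    } else {
      c3 <- exp(log_c3)
      X <- cbind(ev, exp(-c3 * tt), 1)
      sol <- lstsq_minnorm(X, y)
      pred <- drop(X %*% sol$coef)
      list(coef = c(c1 = sol$coef[1], tau = tau, c3 = c3, c2 = sol$coef[2],
                    c4 = sol$coef[3]),
           sse = sum((y - pred)^2),
           evoked = sol$coef[1] * ev,
           trend = drop(X[, 2:3] %*% sol$coef[2:3]))
    }
  }
  cond_obj <- function(id) {
    if (kind == "linear_trend") {
      function(par) cond_solve(id, exp(par[1]))$sse
    } else {
      function(par) cond_solve(id, exp(par[1]), par[2])$sse
    }
  }
  init <- if (kind == "linear_trend") c(log(0.05)) else c(log(0.05), log(2))

  diverged <- FALSE
  if (!share_filter) {
    sols <- lapply(ids, function(id) {
      if (kind == "linear_trend") {
        op <- optim(init, cond_obj(id), method = "Brent",
                    lower = log(grid$dt / 2), upper = log(0.5))
        if (op$convergence != 0) diverged <<- TRUE
        cond_solve(id, exp(op$par[1]))
      } else {
        op <- optim(init, cond_obj(id), method = "Nelder-Mead",
                    control = list(maxit = 500, reltol = 1e-10))
        if (op$convergence != 0) diverged <<- TRUE
        cond_solve(id, exp(op$par[1]), op$par[2])
      }
    })
  } else {
    ## profile one shared tau; other nonlinear params remain per condition
    shared_obj <- function(ltau) {
      sum(vapply(ids, function(id) {
        if (kind == "linear_trend") {
          cond_solve(id, exp(ltau))$sse
        } else {
          op <- optim(log(2), function(lc3) cond_solve(id, exp(ltau), lc3)$sse,
                      method = "Brent", lower = log(1e-3), upper = log(100))
          op$value
        }
      }, numeric(1)))
    }
    op <- optim(log(0.05), shared_obj, method = "Brent",
                lower = log(grid$dt / 2), upper = log(0.5))
    tau_hat <- exp(op$par)
    sols <- lapply(ids, function(id) {
      if (kind == "linear_trend") {
        cond_solve(id, tau_hat)
      } else {
        opc <- optim(log(2), function(lc3) cond_solve(id, tau_hat, lc3)$sse,
                     method = "Brent", lower = log(1e-3), upper = log(100))
        cond_solve(id, tau_hat, opc$par)
      }
    })
  }
  names(sols) <- ids

  per_condition <- dplyr::bind_rows(lapply(ids, function(id) {
    co <- sols[[id]]$coef
    tibble::tibble(condition_id = id, !!!as.list(co))
  }))
  fitted <- dplyr::bind_rows(lapply(ids, function(id) {
    tibble::tibble(
      condition_id = id, time_s = tt,
      fast = sols[[id]]$evoked, slow = sols[[id]]$trend,
      total = sols[[id]]$evoked + sols[[id]]$trend
    )
  }))
  structure(
    list(per_condition = per_condition, fitted = fitted,
         loss = sum(vapply(sols, `[[`, numeric(1), "sse")),
         kind = kind, share_filter = share_filter,
         converged = !diverged, grid = grid,
         conditions = conditions[match(ids, conditions$condition_id), ],
         model = kind),
    class = c("alt_fit", "dn_model_fit")
  )
}
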