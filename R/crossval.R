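#' Leave-one-condition-out cross-validation
#'
#' For each condition: the full model (two-component linear or delayed
#' normalization) is fit to the remaining conditions; the fitted fast
#' parameters predict the held-out condition's stimulus-evoked component; a
#' fresh set of slow-basis weights is then fit to the held-out residual
#' (slow trends are condition-specific, so they are never generalized); and
#' variance explained `1 - SSE/SST` is scored against the held-out curve.
#'
#' `ve_on = "fast"` scores the predicted fast component against the data
#' minus the refit slow component instead; the two computations agree
#' closely on well-behaved data.
#'
#' @inheritParams fit_linear
#' @param model `"linear"` or `"dn"`.
#' @param ve_on Score the full curve (`"full"`) or the fast component only.
#' @param ... Passed to [fit_dn()] (e.g. `restarts`, `seed`).
#' @return Tibble `condition_id, variance_explained, model`.
#' @export
crossval_loco <- function(avg, conditions, fast, slow,
                          model = c("linear", "dn"),
                          ve_on = c("full", "fast"), ...) {
  model <- match.arg(model)
  ve_on <- match.arg(ve_on)
  conditions <- validate_conditions(conditions)
  am <- avg_matrix(avg)
  if (length(am$ids) < 2L) abort("need at least 2 conditions to cross-validate.")
  S <- basis_matrix(slow)
  qrS <- qr(S)
  rows <- lapply(am$ids, function(held) {
    train <- dplyr::filter(avg, .data$condition_id != held)
    fit <- if (model == "linear") {
      fit_linear(train, conditions, fast, slow, share_filter = TRUE)
    } else {
      fit_dn(train, conditions, fast, slow, ...)
    }
    held_cond <- conditions[conditions$condition_id == held, ]
    pred <- if (model == "linear") {
      predict_linear(held_cond,
                     linear_params(fit$params$fast_weights,
                                   setNames(list(numeric(ncol(S))), held)),
                     fast, slow)
    } else {
      p <- fit$params
      predict_dn(held_cond,
                 dn_params(p$numerator_weights, p$denom_gamma, p$sigma,
                           setNames(list(numeric(ncol(S))), held)),
                 fast, slow)
    }
    y <- am$Y[, match(held, am$ids)]
    fast_pred <- pred$fast
    v_held <- qr.coef(qrS, y - fast_pred)
    slow_refit <- drop(S %*% v_held)
    if (ve_on == "full") {
      sse <- sum((y - fast_pred - slow_refit)^2)
      sst <- sum((y - mean(y))^2)
    } else {
      target <- y - slow_refit
      sse <- sum((target - fast_pred)^2)
      sst <- sum((target - mean(target))^2)
    }
    tibble::tibble(
      condition_id = held,
      variance_explained = 1 - sse / sst,
      model = model
    )
  })
  dplyr::bind_rows(rows)
}

#' Choose basis counts by cross-validation
#'
#' Sweeps candidate fast/slow basis counts and scores each pair by mean
#' leave-one-condition-out variance explained under the linear model
#' (cheap, closed form); returns the sweep table sorted best-first.
#'
#' @inheritParams fit_linear
#' @param n_fast_grid,n_slow_grid Candidate counts.
#' @return Tibble `n_fast, n_slow, mean_ve`, best first.
#' @export
select_basis_counts <- function(avg, conditions, grid,
                                n_fast_grid = c(6L, 8L, 10L),
                                n_slow_grid = c(8L, 10L, 12L),
                                coverage_s = if (grid$dt <= 0.025) 0.26 else 0.32) {
  combos <- expand.grid(n_fast = n_fast_grid, n_slow = n_slow_grid)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    fb <- fast_basis(grid, combos$n_fast[i], coverage_s)
    sb <- slow_basis(grid, combos$n_slow[i])
    cv <- crossval_loco(avg, conditions, fb, sb, model = "linear")
    tibble::tibble(
      n_fast = combos$n_fast[i], n_slow = combos$n_slow[i],
      mean_ve = mean(cv$variance_explained)
    )
  })
  dplyr::bind_rows(res) |> dplyr::arrange(dplyr::desc(.data$mean_ve))
}

#' Choose the onset shift by linear-model fit quality
#'
#' Preprocesses the raw trials at each candidate shift and scores the
#' shared-filter linear model loss on the trial averages; smaller is better.
#'
#' @param trials,blanks Raw tidy trial tibbles (see [preprocess_trials()]).
#' @inheritParams fit_linear
#' @param shifts_ms Candidate shifts (must divide the sampling step).
#' @return Tibble `shift_ms, loss`, best first.
#' @export
select_shift <- function(trials, blanks, conditions, fast, slow,
                         shifts_ms = c(0, 10, 20, 30, 40, 50)) {
  res <- lapply(shifts_ms, function(sh) {
    avg <- average_trials(preprocess_trials(trials, blanks, shift_ms = sh))
    fit <- fit_linear(avg, conditions, fast, slow, share_filter = TRUE)
    tibble::tibble(shift_ms = sh, loss = fit$loss)
  })
  dplyr::bind_rows(res) |> dplyr::arrange(.data$loss)
}
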