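#' Read and write tidy trial tables
#'
#' The on-disk format is delimited text with header
#' `condition_id,repeat,time_s,value`, one row per sample per trial.
#' Blank (no-stimulus) trials are encoded with `condition_id == "blank"`.
#' `read_trials()` validates the file: every trial must have a strictly
#' increasing, constant-step time column and all trials must share the same
#' length and step; violations are rejected naming the offending trial.
#'
#' @param path File path.
#' @param trials Tidy trial tibble.
#' @return `read_trials()` returns a list with `trials` (stimulus trials)
#'   and `blanks`.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition_id", "repeat", "time_s", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("'%s': missing column(s): %s", path, toString(miss)))
  }
  df <- validate_trials(df, sprintf("'%s'", path))
  key <- paste(df$condition_id, df[["repeat"]])
  lens <- table(key)
  if (length(unique(lens)) != 1L) {
    bad <- names(lens)[lens != max(lens)][1]
    abort(sprintf("'%s': trial %s has %d samples where others have %d.",
                  path, bad, lens[[bad]], max(lens)))
  }
  dts <- vapply(split(df$time_s, key), function(ts) {
    g <- grid_from_times(ts)
    g$dt
  }, numeric(1))
  if (max(dts) - min(dts) > 1e-9) {
    abort(sprintf("'%s': inconsistent sampling steps across trials.", path))
  }
  list(
    trials = dplyr::filter(df, .data$condition_id != "blank"),
    blanks = dplyr::filter(df, .data$condition_id == "blank")
  )
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  readr::write_csv(
    dplyr::select(trials, "condition_id", "repeat", "time_s", "value"),
    path
  )
  invisible(path)
}

#' Export per-condition summed responses as delimited text
#'
#' Columns: `condition_id, total_on_time_s, summed_response, modality`.
#'
#' @param sums Tibble from [condition_sums()] or an `additivity_result`.
#' @param path Output path.
#' @param modality Label recorded per row (e.g. `"vsdi"`, `"gcamp"`,
#'   `"fmri"`).
#' @export
write_sums <- function(sums, path, modality = "synthetic") {
  if (inherits(sums, "additivity_result")) sums <- sums$table
  out <- tibble::tibble(
    condition_id = sums$condition_id,
    total_on_time_s = sums$on_time_s,
    summed_response = sums$summed_response,
    modality = modality
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an externally supplied per-condition amplitude table
#'
#' Accepts one scalar per condition (e.g. fMRI GLM amplitudes) in the
#' format written by [write_sums()] and returns a tibble usable by
#' [subadditivity_exponent()] / [additive_prediction()].
#'
#' @param path Input path.
#' @return Tibble `condition_id, on_time_s, summed_response, modality`.
#' @export
read_sums <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition_id", "total_on_time_s", "summed_response")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(sprintf("'%s': missing column(s): %s", path, toString(miss)))
  tibble::tibble(
    condition_id = df$condition_id,
    on_time_s = df$total_on_time_s,
    summed_response = df$summed_response,
    modality = if ("modality" %in% names(df)) df$modality else NA_character_
  )
}

## ---- fit serialization -----------------------------------------------------

params_to_list <- function(p) {
  if (inherits(p, "linear_params")) {
    list(kind = "linear", fast_weights = p$fast_weights,
         slow_weights = p$slow_weights)
  } else if (inherits(p, "dn_params")) {
    list(kind = "dn", numerator_weights = p$numerator_weights,
         denom_gamma = unclass(p$denom_gamma), sigma = p$sigma,
         slow_weights = p$slow_weights)
  } else {
    abort("unsupported parameter object.")
  }
}

params_from_list <- function(x) {
  if (identical(x$kind, "linear")) {
    fw <- x$fast_weights
    if (is.list(fw)) fw <- lapply(fw, as.numeric) else fw <- as.numeric(fw)
    linear_params(fw, lapply(x$slow_weights, as.numeric))
  } else if (identical(x$kind, "dn")) {
    g <- x$denom_gamma
    dn_params(
      as.numeric(x$numerator_weights),
      gamma_diff(g$weight1, g$shape1, g$scale1, g$weight2, g$shape2, g$scale2),
      x$sigma,
      lapply(x$slow_weights, as.numeric)
    )
  } else {
    abort("unrecognized parameter kind in JSON.")
  }
}

#' Serialize a fit to JSON and back
#'
#' Records parameters, loss, convergence metadata and (for [fit_dn()]) the
#' loss trace. Round-trips through [params_from_json()] to a parameter
#' bundle usable with the `predict_*` functions.
#'
#' @param fit A `linear_fit` or `dn_fit`.
#' @param path Output path.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "dn_model_fit"))
  payload <- list(
    model = fit$model,
    params = params_to_list(fit$params),
    loss = fit$loss,
    n_iterations = fit$n_iterations,
    converged = isTRUE(fit$converged),
    conditioning_warnings = fit$conditioning_warnings,
    loss_trace = fit$loss_trace
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname fit_to_json
#' @export
params_from_json <- function(path) {
  params_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE)$params)
}
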