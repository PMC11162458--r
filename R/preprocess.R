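## trial tables are tidy: condition_id, repeat, time_s, value
## (blank trials carry condition_id == "blank")

validate_trials <- function(trials, what = "trials") {
  need <- c("condition_id", "repeat", "time_s", "value")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(sprintf("%s missing column(s): %s", what, toString(miss)))
  }
  if (any(!is.finite(trials$value))) abort(sprintf("%s contain non-finite values.", what))
  tibble::as_tibble(trials)
}

trials_grid <- function(trials) {
  one <- dplyr::filter(
    trials,
    .data$condition_id == trials$condition_id[1],
    .data[["repeat"]] == trials[["repeat"]][1]
  )
  grid_from_times(one$time_s)
}

#' Preprocess raw trial time courses
#'
#' Applies the three standard preprocessing steps before any model fitting:
#'
#' 1. **Blank subtraction** — the mean time course over blank (no-stimulus)
#'    trials is subtracted from every stimulus-present trial, removing
#'    stimulus-independent effects shared across trials (heartbeat artifact,
#'    dye bleaching, ...).
#' 2. **Onset alignment** — each trial is advanced by `shift_ms`
#'    (default 30 ms), discarding the conduction latency between stimulus
#'    and cortical response; the vacated tail is zero-padded. The shift must
#'    be an integer number of samples.
#' 3. **Baseline zeroing** — the first sample is subtracted from the whole
#'    time course, so every trial starts at exactly 0.
#'
#' @param trials Tidy trial tibble (`condition_id, repeat, time_s, value`);
#'   stimulus trials only, or a mixed table from which `condition_id ==
#'   "blank"` rows are taken as blanks when `blanks` is NULL.
#' @param blanks Tidy tibble of blank trials (>= 1 trial).
#' @param shift_ms Onset shift in milliseconds.
#' @return Preprocessed stimulus trials in the same tidy format.
#' @export
preprocess_trials <- function(trials, blanks = NULL, shift_ms = 30) {
  trials <- validate_trials(trials)
  if (is.null(blanks)) {
    blanks <- dplyr::filter(trials, .data$condition_id == "blank")
    trials <- dplyr::filter(trials, .data$condition_id != "blank")
  }
  blanks <- validate_trials(blanks, "blanks")
  if (nrow(blanks) == 0L) abort("at least one blank trial is required.")
  grid <- trials_grid(trials)
  k <- shift_ms / 1000 / grid$dt
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf("shift_ms = %g is not a multiple of dt = %g ms.", shift_ms, grid$dt * 1000))
  }
  k <- as.integer(round(k))

  blank_mean <- blanks |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(blank = mean(.data$value), .groups = "drop")
  if (nrow(blank_mean) != grid$n_samples) {
    abort("blank trials are not on the same grid as stimulus trials.")
  }

  trials |>
    dplyr::left_join(blank_mean, by = "time_s") |>
    dplyr::mutate(value = .data$value - .data$blank, blank = NULL) |>
    dplyr::group_by(.data$condition_id, .data[["repeat"]]) |>
    dplyr::mutate(value = shift_zero(.data$value, k)) |>
    dplyr::mutate(value = .data$value - .data$value[1]) |>
    dplyr::ungroup()
}

## advance a series by k samples, zero-padding the tail
shift_zero <- function(v, k) {
  n <- length(v)
  if (k == 0L) return(v)
  if (k >= n) return(numeric(n))
  c(v[(k + 1L):n], numeric(k))
}

#' Average trials within condition
#'
#' @param trials Tidy trial tibble.
#' @return Tibble `condition_id, time_s, value` (per-condition mean curves).
#' @export
average_trials <- function(trials) {
  trials <- validate_trials(trials)
  trials |>
    dplyr::group_by(.data$condition_id, .data$time_s) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$condition_id, .data$time_s)
}

#' Bootstrap trial-mean time courses
#'
#' Resamples repeats with replacement within each condition and recomputes
#' the per-condition mean curve, `n_boot` times (default 50). Deterministic
#' under a fixed seed.
#'
#' @param trials Tidy trial tibble.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer RNG seed.
#' @return Tibble `boot, condition_id, time_s, value`.
#' @export
bootstrap_means <- function(trials, n_boot = 50L, seed = 0L) {
  trials <- validate_trials(trials)
  if (n_boot < 1L) abort("`n_boot` must be at least 1.")
  set.seed(as.integer(seed))
  by_cond <- split(trials, trials$condition_id)
  out <- lapply(seq_len(n_boot), function(b) {
    resampled <- lapply(by_cond, function(df) {
      reps <- unique(df[["repeat"]])
      draw <- sample(reps, length(reps), replace = TRUE)
      dplyr::bind_rows(lapply(seq_along(draw), function(i) {
        d <- df[df[["repeat"]] == draw[i], ]
        d[["repeat"]] <- i
        d
      }))
    })
    avg <- average_trials(dplyr::bind_rows(resampled))
    avg$boot <- b
    avg
  })
  dplyr::bind_rows(out) |>
    dplyr::select("boot", "condition_id", "time_s", "value")
}
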