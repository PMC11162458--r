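#' Temporal stimulus conditions
#'
#' `condition_set()` enumerates the canonical 12 temporal conditions used in
#' the additivity experiments: 6 single pulses of one image with durations
#' doubling from 20 to 640 ms, and 6 double pulses (two 160 ms presentations
#' of the same image) with inter-stimulus intervals (ISIs) doubling from 20
#' to 640 ms. All conditions are at full contrast by default.
#'
#' Note that the 320 ms single pulse is, sample for sample, the double-pulse
#' stimulus with 0 ISI, which anchors the additivity logic.
#'
#' @param contrast Scalar contrast in (0, 1] applied to every condition.
#'
#' @return A tibble with one row per condition and columns
#'   `condition_id`, `pulse_durations_ms` (list-column of 1 or 2 durations),
#'   `isi_ms` (`NA` for single pulses), `contrast`.
#' @export
#' @examples
#' condition_set()
condition_set <- function(contrast = 1) {
  durations <- c(20, 40, 80, 160, 320, 640)
  single <- tibble::tibble(
    condition_id = sprintf("dur%03d", durations),
    pulse_durations_ms = lapply(durations, identity),
    isi_ms = NA_real_,
    contrast = contrast
  )
  double <- tibble::tibble(
    condition_id = sprintf("isi%03d", durations),
    pulse_durations_ms = rep(list(c(160, 160)), 6L),
    isi_ms = as.numeric(durations),
    contrast = contrast
  )
  validate_conditions(dplyr::bind_rows(single, double))
}

#' Build a single custom condition row
#'
#' @param condition_id Short unique label.
#' @param pulse_durations_ms One or two positive pulse durations (ms). Double
#'   pulses must both last 160 ms, matching the experimental design.
#' @param isi_ms Inter-stimulus interval in ms (only for double pulses).
#' @param contrast Scalar in (0, 1].
#' @return A one-row conditions tibble.
#' @export
stimulus_condition <- function(condition_id, pulse_durations_ms, isi_ms = NA_real_,
                               contrast = 1) {
  validate_conditions(tibble::tibble(
    condition_id = condition_id,
    pulse_durations_ms = list(as.numeric(pulse_durations_ms)),
    isi_ms = as.numeric(isi_ms),
    contrast = contrast
  ))
}

validate_conditions <- function(conds) {
  stopifnot(is.data.frame(conds))
  need <- c("condition_id", "pulse_durations_ms", "isi_ms", "contrast")
  miss <- setdiff(need, names(conds))
  if (length(miss)) abort(paste0("conditions missing column(s): ", toString(miss)))
  if (anyDuplicated(conds$condition_id)) abort("condition_id values must be unique.")
  for (i in seq_len(nrow(conds))) {
    p <- conds$pulse_durations_ms[[i]]
    id <- conds$condition_id[i]
    if (!length(p) %in% 1:2 || any(!is.finite(p)) || any(p <= 0)) {
      abort(sprintf("condition '%s': pulse_durations_ms must be 1 or 2 positive values.", id))
    }
    if (length(p) == 1L && !is.na(conds$isi_ms[i])) {
      abort(sprintf("condition '%s': single-pulse conditions take no ISI.", id))
    }
    if (length(p) == 2L) {
      if (is.na(conds$isi_ms[i]) || conds$isi_ms[i] < 0) {
        abort(sprintf("condition '%s': double-pulse conditions need a nonnegative ISI.", id))
      }
      if (!all(p == 160)) {
        abort(sprintf("condition '%s': double-pulse durations must both be 160 ms.", id))
      }
    }
    ct <- conds$contrast[i]
    if (!is.finite(ct) || ct < 0 || ct > 1) {
      abort(sprintf("condition '%s': contrast must lie in [0, 1].", id))
    }
  }
  tibble::as_tibble(conds)
}

#' Total stimulus-on time of each condition
#'
#' The on-time is the sum of pulse durations; the ISI contributes nothing,
#' so every double-pulse condition has 0.32 s of stimulation regardless of
#' its interval. This is the abscissa `x` of the power-law additivity fit.
#'
#' @param conditions A conditions tibble (see [condition_set()]).
#' @return The input with an added `on_time_s` column.
#' @export
#' @examples
#' total_on_time(condition_set())
total_on_time <- function(conditions) {
  conditions <- validate_conditions(conditions)
  conditions$on_time_s <- vapply(
    conditions$pulse_durations_ms, function(p) sum(p) / 1000, numeric(1)
  )
  conditions
}

#' Render conditions as sampled stimulus time courses
#'
#' Discretizes each condition into a binary-in-time vector `s(t)` on the
#' grid: `contrast` over stimulus-on samples starting at the grid's onset
#' index, zero elsewhere, with `isi_ms` of zeros between the two pulses of a
#' double-pulse condition.
#'
#' Durations and ISIs must be integer multiples of `grid$dt` (to 1e-9 s).
#' With `fractional = TRUE`, conditions that do not divide the sampling step
#' (e.g. a 20 ms pulse on the 50 ms GCaMP grid) are rendered on a 10x finer
#' internal grid and box-averaged down, yielding fractional on-sample values
#' that conserve contrast-weighted on-time.
#'
#' @param conditions Conditions tibble.
#' @param grid A [time_grid()].
#' @param fractional Allow sub-sample pulse edges via fine-grid box averaging.
#' @return A tibble `condition_id, time_s, s` in long (tidy) form.
#' @export
#' @examples
#' render_stimulus(condition_set()[1, ], vsdi_grid())
render_stimulus <- function(conditions, grid, fractional = FALSE) {
  conditions <- validate_conditions(conditions)
  stopifnot(inherits(grid, "time_grid"))
  out <- lapply(seq_len(nrow(conditions)), function(i) {
    tibble::tibble(
      condition_id = conditions$condition_id[i],
      time_s = grid_times(grid),
      s = render_one(
        conditions$pulse_durations_ms[[i]],
        conditions$isi_ms[i],
        conditions$contrast[i],
        grid,
        fractional,
        conditions$condition_id[i]
      )
    )
  })
  dplyr::bind_rows(out)
}

## single condition -> numeric vector of length grid$n_samples
render_one <- function(pulses_ms, isi_ms, contrast, grid, fractional, id) {
  dt_ms <- grid$dt * 1000
  segments_ms <- if (length(pulses_ms) == 2L) {
    c(pulses_ms[1], -isi_ms, pulses_ms[2]) # negative marks an off segment
  } else {
    pulses_ms
  }
  # representable to within 1e-9 s
  divisible <- function(x) abs(x - round(x / dt_ms) * dt_ms) < 1e-6
  if (all(vapply(abs(segments_ms), divisible, logical(1)))) {
    v <- numeric(grid$n_samples)
    pos <- grid$onset_index # 0-based cursor
    for (seg in segments_ms) {
      n_on <- as.integer(round(abs(seg) / dt_ms))
      if (pos + n_on > grid$n_samples) {
        abort(sprintf(
          "condition '%s': stimulus extends past trial end (needs sample %d of %d).",
          id, pos + n_on, grid$n_samples
        ))
      }
      if (seg > 0 && n_on > 0) v[(pos + 1L):(pos + n_on)] <- contrast
      pos <- pos + n_on
    }
    return(v)
  }
  if (!fractional) {
    bad <- segments_ms[!vapply(abs(segments_ms), divisible, logical(1))][1]
    abort(sprintf(
      "condition '%s': duration/ISI of %g ms is not a multiple of dt = %g ms; set `fractional = TRUE` to box-average on a finer grid.",
      id, abs(bad), dt_ms
    ))
  }
  ## render on 10x finer grid, then average each block of 10 samples
  fine <- time_grid(grid$dt / 10, grid$n_samples * 10L, grid$onset_index * 10L)
  vf <- render_one(pulses_ms, isi_ms, contrast, fine, fractional = FALSE, id = id)
  colMeans(matrix(vf, nrow = 10L))
}

#' Serialize conditions to/from JSON
#'
#' @param conditions Conditions tibble.
#' @param path File path; for `conditions_to_json` with `path = NULL` the
#'   JSON string is returned instead of written.
#' @return `conditions_from_json` returns a validated conditions tibble.
#' @export
conditions_to_json <- function(conditions, path = NULL) {
  conditions <- validate_conditions(conditions)
  recs <- lapply(seq_len(nrow(conditions)), function(i) {
    list(
      condition_id = conditions$condition_id[i],
      pulse_durations_ms = conditions$pulse_durations_ms[[i]],
      isi_ms = if (is.na(conditions$isi_ms[i])) NULL else conditions$isi_ms[i],
      contrast = conditions$contrast[i]
    )
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname conditions_to_json
#' @export
conditions_from_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validate_conditions(tibble::tibble(
    condition_id = vapply(recs, `[[`, character(1), "condition_id"),
    pulse_durations_ms = lapply(recs, function(r) as.numeric(r$pulse_durations_ms)),
    isi_ms = vapply(recs, function(r) {
      if (is.null(r$isi_ms)) NA_real_ else as.numeric(r$isi_ms)
    }, numeric(1)),
    contrast = vapply(recs, function(r) {
      if (is.null(r$contrast)) 1 else as.numeric(r$contrast)
    }, numeric(1))
  ))
}
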