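#' Canonical delayed-normalization ground truth
#'
#' A documented VSDI-style parameter set used as the recovery-test fixture
#' and for the package's simulations. Its defining properties: the
#' numerator filter `f_l` peaks at 50 ms with a small late negative lobe
#' (pooled-membrane-potential filters for sustained stimuli are mildly
#' biphasic); the denominator filter `f_n` is biphasic with its positive
#' peak at 70 ms and negative peak near 150 ms; normalization is strong
#' enough at full contrast to produce duration-dependent gain while leaving
#' temporal summation near-additive (the biphasic-denominator regime).
#'
#' The numerator weights are the least-squares projection of a
#' difference-of-Gammas target shape onto the fast basis, computed at call
#' time, so the filter is exactly representable by the model.
#'
#' @param grid A [time_grid()]; must resolve a 50 ms peak (`dt <= 50 ms`).
#' @param fast Optional fast `basis_set` (defaults to the modality default).
#' @return A [dn_params()] object (no slow weights).
#' @export
#' @examples
#' truth <- default_dn_truth(vsdi_grid())
#' time_to_peak(gamma_diff_filter(truth$denom_gamma, vsdi_grid()))
default_dn_truth <- function(grid = vsdi_grid(), fast = fast_basis(grid)) {
  stopifnot(inherits(grid, "time_grid"))
  if (grid$dt > 0.050 + 1e-12) {
    abort("grid is too coarse to express a 50 ms filter peak (need dt <= 50 ms).")
  }
  tt <- grid_times(grid)
  ## target numerator: unit-peak Gamma peaking at 50 ms minus a small,
  ## slower negative lobe (peak ~160 ms); f_l stays mostly monophasic
  target <- gamma_kernel(tt, shape = 3, scale = 0.025) -
    0.20 * gamma_kernel(tt, shape = 5, scale = 0.040)
  target[tt > fast$coverage_s] <- 0
  u <- lstsq_minnorm(basis_matrix(fast), target)$coef
  ## amplitude scale: the peak evoked response over the canonical 12
  ## conditions is 1 response unit at full contrast (set once)
  u <- u * 1.173342
  g <- gamma_diff(
    weight1 = 1.0, shape1 = 4, scale1 = 0.08 / 3,
    weight2 = 0.8, shape2 = 12, scale2 = 0.13 / 11
  )
  dn_params(numerator_weights = u, denom_gamma = g, sigma = 0.04)
}

#' Purely linear ground truth
#'
#' The same numerator filter as [default_dn_truth()] but with no
#' normalization: a convenient exactly additive generator.
#'
#' @inheritParams default_dn_truth
#' @return A [linear_params()] object (no slow weights).
#' @export
default_linear_truth <- function(grid = vsdi_grid(), fast = fast_basis(grid)) {
  dn <- default_dn_truth(grid, fast)
  linear_params(fast_weights = dn$numerator_weights / dn$sigma,
                slow_weights = list())
}

#' Specification for the synthetic trial generator
#'
#' Bundles everything [simulate_trials()] needs: the sampling grid, the
#' generating model and its ground-truth fast parameters, repeat counts,
#' and the amplitudes of the three nuisance ingredients the analysis must
#' cope with — a per-trial random slow trend (an order of magnitude slower
#' than the evoked dynamics), a deterministic artifact shared by every
#' trial including blanks (heartbeat-locked oscillation plus a bleaching
#' drift), and i.i.d. Gaussian sample noise.
#'
#' @param grid A [time_grid()].
#' @param generator_kind `"dn"` or `"linear"`.
#' @param truth_params [dn_params()] or [linear_params()] for the fast
#'   component.
#' @param n_repeats Repeats per condition (default 8; see
#'   `seven_repeat_conditions`).
#' @param seven_repeat_conditions Conditions recorded with one fewer repeat
#'   (two of the twelve, mirroring the experimental yield).
#' @param noise_sd Per-sample Gaussian noise SD (response units).
#' @param slow_amplitude RMS amplitude of the per-trial slow trend.
#' @param artifact_amplitude Amplitude of the shared artifact.
#' @param n_blank_trials Number of blank trials.
#' @param seed Integer RNG seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(grid = vsdi_grid(),
                           generator_kind = c("dn", "linear"),
                           truth_params = NULL,
                           n_repeats = 8L,
                           seven_repeat_conditions = c("isi320", "isi640"),
                           noise_sd = 0.10,
                           slow_amplitude = 0.10,
                           artifact_amplitude = 0.20,
                           n_blank_trials = 16L,
                           seed = 0L) {
  generator_kind <- match.arg(generator_kind)
  if (is.null(truth_params)) {
    truth_params <- if (generator_kind == "dn") {
      default_dn_truth(grid)
    } else {
      default_linear_truth(grid)
    }
  }
  if (n_repeats < 1L) abort("`n_repeats` must be >= 1.")
  if (noise_sd < 0 || slow_amplitude < 0 || artifact_amplitude < 0) {
    abort("noise and amplitude parameters must be nonnegative.")
  }
  structure(
    list(grid = grid, generator_kind = generator_kind,
         truth_params = truth_params, n_repeats = as.integer(n_repeats),
         seven_repeat_conditions = seven_repeat_conditions,
         noise_sd = noise_sd, slow_amplitude = slow_amplitude,
         artifact_amplitude = artifact_amplitude,
         n_blank_trials = as.integer(n_blank_trials),
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

## random slow trend: harmonics 1-4 of the trial window (<= ~3.3 Hz on the
## VSDI grid), 1/k-weighted coefficients, rescaled to exact RMS amplitude
random_slow_trend <- function(grid, amplitude) {
  if (amplitude == 0) return(numeric(grid$n_samples))
  tt <- grid_times(grid)
  dur <- grid$n_samples * grid$dt
  k <- 1:4
  a <- rnorm(4) / k
  b <- rnorm(4) / k
  trend <- numeric(grid$n_samples)
  for (i in k) {
    trend <- trend + a[i] * cos(2 * pi * i * tt / dur) +
      b[i] * sin(2 * pi * i * tt / dur)
  }
  trend * amplitude / sqrt(mean(trend^2))
}

## deterministic shared artifact: heartbeat-locked oscillation + bleaching drift
shared_artifact <- function(grid, amplitude) {
  tt <- grid_times(grid)
  dur <- grid$n_samples * grid$dt
  amplitude * (0.5 * sin(2 * pi * 2.5 * tt) - tt / dur)
}

#' Generate a synthetic trial-resolved dataset
#'
#' Each stimulus trial is the sum of (1) the noiseless fast component from
#' the ground-truth model, (2) a per-trial random slow trend, (3) the
#' shared deterministic artifact, and (4) i.i.d. Gaussian noise. Blank
#' trials contain everything except the fast component. The output is
#' bit-reproducible for a fixed `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @param conditions Conditions tibble (default the canonical 12).
#' @return List with tidy tibbles `trials`, `blanks`
#'   (`condition_id, repeat, time_s, value`) and `ground_truth`
#'   (`condition_id, time_s, fast` — the noiseless fast component).
#' @export
#' @examples
#' spec <- generator_spec(noise_sd = 0, slow_amplitude = 0, artifact_amplitude = 0)
#' d <- simulate_trials(spec)
#' nrow(d$trials)
simulate_trials <- function(spec, conditions = condition_set()) {
  stopifnot(inherits(spec, "generator_spec"))
  conditions <- validate_conditions(conditions)
  grid <- spec$grid
  tt <- grid_times(grid)
  fractional <- needs_fractional(conditions, grid)

  pred <- if (spec$generator_kind == "dn") {
    predict_dn(conditions, spec$truth_params, fast_basis(grid), slow = NULL,
               grid = grid, fractional = fractional)
  } else {
    predict_linear(conditions, spec$truth_params, fast_basis(grid), slow = NULL,
                   grid = grid, fractional = fractional)
  }
  ground_truth <- dplyr::select(pred, "condition_id", "time_s", "fast")

  artifact <- shared_artifact(grid, spec$artifact_amplitude)
  set.seed(spec$seed)

  trial_rows <- list()
  for (id in conditions$condition_id) {
    n_rep <- spec$n_repeats - (id %in% spec$seven_repeat_conditions)
    fastc <- ground_truth$fast[ground_truth$condition_id == id]
    for (r in seq_len(n_rep)) {
      v <- fastc +
        random_slow_trend(grid, spec$slow_amplitude) +
        artifact +
        rnorm(grid$n_samples, sd = spec$noise_sd)
      trial_rows[[length(trial_rows) + 1L]] <- tibble::tibble(
        condition_id = id, `repeat` = r, time_s = tt, value = v
      )
    }
  }
  blank_rows <- lapply(seq_len(spec$n_blank_trials), function(r) {
    v <- random_slow_trend(grid, spec$slow_amplitude) +
      artifact +
      rnorm(grid$n_samples, sd = spec$noise_sd)
    tibble::tibble(condition_id = "blank", `repeat` = r, time_s = tt, value = v)
  })
  list(
    trials = dplyr::bind_rows(trial_rows),
    blanks = dplyr::bind_rows(blank_rows),
    ground_truth = ground_truth
  )
}

needs_fractional <- function(conditions, grid) {
  dt_ms <- grid$dt * 1000
  any(vapply(seq_len(nrow(conditions)), function(i) {
    segs <- c(conditions$pulse_durations_ms[[i]], conditions$isi_ms[i])
    segs <- segs[is.finite(segs)]
    any(abs(segs - round(segs / dt_ms) * dt_ms) > 1e-6)
  }, logical(1)))
}

#' Write a generated dataset with its provenance sidecar
#'
#' Writes `trials` and `blanks` in the tidy delimited format (see
#' [write_trials()]) plus a JSON sidecar recording the generator settings
#' and seed.
#'
#' @param dataset Output of [simulate_trials()].
#' @param spec The [generator_spec()] that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials(dataset$trials, file.path(dir, "trials.csv"))
  write_trials(dataset$blanks, file.path(dir, "blanks.csv"))
  readr::write_csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"))
  side <- spec
  side$grid <- list(dt = spec$grid$dt, n_samples = spec$grid$n_samples,
                    onset_index = spec$grid$onset_index)
  side$truth_params <- params_to_list(spec$truth_params)
  jsonlite::write_json(unclass(side), file.path(dir, "generator_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
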