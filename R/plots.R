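#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types, plus
#' `plot_trials()` for raw tidy trial tables.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot basis_set
#' @export
autoplot.basis_set <- function(object, ...) {
  ggplot2::ggplot(tidy.basis_set(object),
                  ggplot2::aes(.data$time_s, .data$value, colour = .data$basis_fn)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("%s raised-cosine basis (%d functions)",
                      object$kind, ncol(object$matrix))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot filter_shape
#' @export
autoplot.filter_shape <- function(object, ...) {
  df <- tibble::tibble(time_s = grid_times(object$grid), value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "filter amplitude") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param data Optional tidy averaged data (`condition_id, time_s, value`)
#'   overlaid as points behind the fitted curves.
#' @method autoplot dn_model_fit
#' @export
autoplot.dn_model_fit <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object$fitted, ggplot2::aes(.data$time_s, .data$total))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(.data$time_s, .data$value),
      size = 0.4, colour = "grey60"
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$fast), colour = "steelblue") +
    ggplot2::geom_line(colour = "black") +
    ggplot2::facet_wrap(~condition_id) +
    ggplot2::labs(
      x = "time (s)", y = "response",
      title = sprintf("%s model fit (black: total, blue: fast component)",
                      object$model)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot additivity_result
#' @export
autoplot.additivity_result <- function(object, ...) {
  df <- object$table
  xr <- range(df$on_time_s)
  powline <- tibble::tibble(
    on_time_s = exp(seq(log(xr[1]), log(xr[2]), length.out = 50))
  )
  powline$fit <- object$a * powline$on_time_s^object$c
  ggplot2::ggplot(df, ggplot2::aes(.data$on_time_s, .data$summed_response)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$additive_pred), linetype = "dotted"
    ) +
    ggplot2::geom_line(data = powline, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "total stimulus-on time (s)", y = "summed response",
      title = sprintf("temporal additivity: c = %.3f", object$c),
      subtitle = "dotted: additive prediction; red: fitted power law"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot contrast_sim
#' @export
autoplot.contrast_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$curves,
    ggplot2::aes(.data$time_s, .data$response,
                 colour = factor(.data$contrast), group = .data$contrast)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "predicted response", colour = "contrast",
      title = sprintf("DN response to a %g ms pulse across contrasts",
                      object$duration_ms)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param trials Tidy trial tibble.
#' @export
plot_trials <- function(trials, ...) {
  trials <- validate_trials(trials)
  ggplot2::ggplot(
    trials,
    ggplot2::aes(.data$time_s, .data$value, group = .data[["repeat"]])
  ) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~condition_id) +
    ggplot2::labs(x = "time (s)", y = "response") +
    ggplot2::theme_minimal()
}
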