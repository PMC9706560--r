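# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a nearest-neighbor parameter set
#'
#' Term magnitudes with standard-error bars, coloured by the number of
#' Watson-Crick hydrogen bonds of the stack (initiation and terminal-GC
#' terms shown separately).
#'
#' @param object An `nn_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nn_fit
#' @export
autoplot.nn_fit <- function(object, ...) {
  d <- object$terms |>
    dplyr::mutate(
      magnitude = abs(.data$estimate),
      group = dplyr::if_else(is.na(.data$wc_hbonds), "other",
                             paste0(.data$wc_hbonds, " H-bonds")),
      term = factor(.data$term, levels = .data$term)
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$magnitude,
                                  fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$magnitude - .data$se,
                   ymax = .data$magnitude + .data$se),
      width = 0.3
    ) +
    ggplot2::labs(x = NULL, fill = NULL,
                  y = expression(-Delta * chi ~ "(magnitude)")) +
    ggplot2::theme_minimal()
}

#' Plot a van't Hoff fit
#'
#' ln K against 1/T with the fitted line.
#'
#' @param object A `vant_hoff` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vant_hoff
#' @export
autoplot.vant_hoff <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$inv_T,
                                            y = .data$ln_K)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = expression(1 / T ~ (K^-1)), y = expression(ln ~ K)) +
    ggplot2::theme_minimal()
}

#' Plot an alpha (duplexed-fraction) melting curve
#'
#' @param data A tibble with `temperature_K` and `alpha` (from
#'   [normalize_to_alpha()]); the melting point, if defined, is marked.
#' @return A ggplot.
#' @export
plot_alpha_curve <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$temperature_K,
                                          y = .data$alpha)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (K)", y = expression(alpha)) +
    ggplot2::theme_minimal()
  tm <- tryCatch(melting_temperature(data), error = function(e) NA_real_)
  if (!is.na(tm)) {
    p <- p + ggplot2::geom_vline(xintercept = tm, linetype = "dashed")
  }
  p
}

#' Plot melting-event occurrence curves
#'
#' Occurrences per nanosecond of events of at least a given duration,
#' one line per group.
#'
#' @param data An occurrence table from [event_occurrence_curve()],
#'   optionally with a `group` column (e.g. terminal AT vs GC).
#' @return A ggplot.
#' @export
plot_occurrence_curve <- function(data) {
  aes <- if ("group" %in% names(data)) {
    ggplot2::aes(x = .data$threshold_ns, y = .data$occurrences_per_ns,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$threshold_ns, y = .data$occurrences_per_ns)
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Event duration threshold (ns)",
                  y = "Occurrences per ns") +
    ggplot2::theme_minimal()
}
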