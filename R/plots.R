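#' Plot a sweep table
#'
#' Arousal count against T_sk threshold; when a `breakpoint_fit` is supplied
#' the continuous two-segment fit and the breakpoint are overlaid.
#'
#' @param object A `sweep_table`.
#' @param breakpoint Optional `breakpoint_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_table <- function(object, breakpoint = NULL, ...) {
  p <- ggplot2::ggplot(object$counts,
                       ggplot2::aes(x = .data$threshold_c, y = .data$n_arousals)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(T[sk] ~ "threshold (" * degree * "C)"),
                  y = "Total arousals detected") +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint)) {
    x <- object$counts$threshold_c
    y <- object$counts$n_arousals
    h <- pmax(x - breakpoint$psi, 0)
    fit <- lm(y ~ x + h)
    xg <- seq(min(x), max(x), by = 0.05)
    pred <- tibble::tibble(
      threshold_c = xg,
      n_arousals = coef(fit)[1] + coef(fit)[2] * xg +
        coef(fit)[3] * pmax(xg - breakpoint$psi, 0))
    p <- p +
      ggplot2::geom_line(data = pred, colour = "steelblue") +
      ggplot2::geom_vline(xintercept = breakpoint$psi, linetype = "dashed")
  }
  p
}

#' @rdname autoplot.sweep_table
#' @export
autoplot.calibration <- function(object, ...) {
  autoplot(object$sweep, breakpoint = object$breakpoint) +
    ggplot2::geom_vline(xintercept = as.numeric(object$selected),
                        colour = "firebrick", linetype = "dotted")
}

#' Plot skin-temperature traces with detected bouts
#'
#' @param traces T_sk tibble (optionally several bats; facetted).
#' @param bouts Optional bout tibble; arousal intervals are shaded.
#' @param threshold Optional threshold line, degrees C.
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, bouts = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$time_min / 1440, y = .data$tsk_c)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~bat_id) +
    ggplot2::labs(x = "Day of hibernation",
                  y = expression(T[sk] ~ "(" * degree * "C)")) +
    ggplot2::theme_minimal()
  if (!is.null(bouts)) {
    ar <- bouts[bouts$kind == "arousal", , drop = FALSE]
    if (nrow(ar)) {
      p <- p + ggplot2::geom_rect(
        data = ar,
        ggplot2::aes(xmin = .data$start_min / 1440, xmax = .data$end_min / 1440,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, alpha = 0.15, fill = "firebrick")
    }
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Boxplot of huddle-size index by treatment
#'
#' @param hsi_values Tibble with `treatment`, `hsi`.
#' @return A ggplot object.
#' @export
plot_hsi <- function(hsi_values) {
  ggplot2::ggplot(hsi_values, ggplot2::aes(x = .data$treatment, y = .data$hsi)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Humidity treatment", y = "Huddle size index (% of image)") +
    ggplot2::theme_minimal()
}
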