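# ggplot2 displays for transfer functions and condition matrices.

#' @importFrom ggplot2 autoplot ggplot aes geom_line scale_x_log10 labs
#'   facet_wrap facet_grid vars theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a transfer function
#'
#' Magnitude (dB) and, optionally, unwrapped phase (cycles) against
#' frequency on a log axis.
#'
#' @param object An `ear_tf`.
#' @param phase Include the phase panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ear_tf <- function(object, phase = FALSE, ...) {
  df <- tibble(frequency_hz = object$frequency_hz,
               magnitude_db = object$magnitude_db,
               phase_cycles = object$phase_cycles)
  ttl <- sprintf("%s, %s (%s)", attr(object, "node"), attr(object, "kind"),
                 attr(object, "condition"))
  if (phase) {
    long <- tidyr::pivot_longer(df, c("magnitude_db", "phase_cycles"),
                                names_to = "panel", values_to = "value")
    ggplot(long, aes(x = .data$frequency_hz, y = .data$value)) +
      geom_line() +
      facet_wrap(vars(.data$panel), ncol = 1, scales = "free_y") +
      scale_x_log10() +
      labs(x = "frequency (Hz)", y = NULL, title = ttl) +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$frequency_hz, y = .data$magnitude_db)) +
      geom_line() +
      scale_x_log10() +
      labs(x = "frequency (Hz)", y = "magnitude (dB)", title = ttl) +
      theme_minimal()
  }
}

#' Plot every curve of a condition matrix
#'
#' Magnitude curves for all simulated ear conditions, one panel per
#' measurement site, colour per condition.
#'
#' @param object A `condition_matrix` from [run_condition_matrix()].
#' @param kind Transfer kind to display (default the relative ratio).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_matrix <- function(object, kind = "relative", ...) {
  df <- tidy(object)
  df <- df[df$kind == kind, ]
  ggplot(df, aes(x = .data$frequency_hz, y = .data$magnitude_db,
                 colour = .data$condition)) +
    geom_line() +
    facet_wrap(vars(.data$site)) +
    scale_x_log10() +
    labs(x = "frequency (Hz)", y = "magnitude (dB)",
         colour = "condition",
         title = sprintf("%s velocity transfer, bone conduction", kind)) +
    theme_minimal()
}

#' @rdname autoplot.condition_matrix
#' @export
plot_condition_matrix <- function(object, kind = "relative", ...) {
  autoplot.condition_matrix(object, kind = kind, ...)
}
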