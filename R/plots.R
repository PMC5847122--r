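#' Plot an accuracy curve
#'
#' Draws the accuracy objective against training sample size (log scale),
#' one line per combination scheme.
#'
#' @param object An [accuracy_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  objective <- attr(object, "objective") %||% "value"
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$n, y = .data$value, colour = .data$scheme)
  ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_x_log10(labels = function(x) format(x, big.mark = ",", scientific = FALSE)) +
    ggplot2::labs(
      x = "training sample size",
      y = toupper(objective),
      colour = "score"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.accuracy_curve <- function(x, ...) print(autoplot(x, ...))
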