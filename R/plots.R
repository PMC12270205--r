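# Trajectory visualization: per-subject spaghetti plus group-level fits.

#' Plot longitudinal trajectories by group
#'
#' Thin lines show individual subjects; thick lines with 95% confidence
#' bands show per-group linear (or quadratic) trends.
#'
#' @param data Long-format table: `subject_id`, `group`, `time`, `value`.
#' @param outcome Optional outcome name to filter on (when the table carries
#'   an `outcome` column).
#' @param order Trend order for the group fits.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, outcome = NULL,
                              order = c("linear", "quadratic")) {
  order <- match.arg(order)
  if (!is.null(outcome) && "outcome" %in% names(data)) {
    data <- data[data$outcome == outcome, , drop = FALSE]
  }
  fml <- if (order == "linear") y ~ x else y ~ x + I(x^2)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_smooth(method = "lm", formula = fml, se = TRUE,
                         linewidth = 1.1) +
    ggplot2::labs(x = "Years since baseline", y = outcome %||% "value",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
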