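#' Plot a tension trace with detected events
#'
#' Force against time, with detected pull events shaded and peaks marked,
#' colored by attributed direction.
#'
#' @param trace A `leash_trace`.
#' @param events Optional event tibble from [detect_pull_events()].
#' @param threshold Optional threshold (kgf) drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$force_kgf)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "tension (kgf)",
                  title = trace_session(trace))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  if (!is.null(events) && nrow(events)) {
    p <- p +
      ggplot2::geom_rect(
        data = events, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf, fill = .data$direction),
        alpha = 0.15) +
      ggplot2::geom_point(
        data = events, inherit.aes = FALSE,
        ggplot2::aes(x = .data$start_s + (.data$end_s - .data$start_s) / 2,
                     y = .data$peak_kgf, colour = .data$direction),
        size = 1)
  }
  p
}

#' Plot a behavior summary
#'
#' Bar chart of point-behavior rates and state-behavior time fractions,
#' faceted by measure.
#'
#' @param summary Tibble from [summarize_behaviors()].
#' @return A ggplot object.
#' @export
plot_behavior_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$behavior, .data$value),
                               y = .data$value, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "rate (events/s) or time (%)")
}

#' BIC path of a backward elimination
#'
#' @param object A `walk_elimination`.
#' @param ... Unused.
#' @return A ggplot object showing BIC at each elimination step.
#' @export
autoplot.walk_elimination <- function(object, ...) {
  df <- tibble::tibble(step = seq_along(object$bic_path) - 1L,
                       bic = object$bic_path,
                       removed = c("(full model)", object$trace$removed))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$removed),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "predictors removed", y = "BIC (ML fit)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
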