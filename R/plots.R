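#' Plot daily per-region per-topic message counts
#'
#' One line per topic, faceted by region — the day-by-day monitoring view
#' the change detector operates on.
#'
#' @param object An `osn_daily_counts` tibble from [aggregate_daily()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.osn_daily_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$count,
                                       colour = .data$topic)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$region), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "messages/day", colour = "topic") +
    ggplot2::theme_minimal()
}

#' Plot normalized emotion series around an event
#'
#' Each emotion's daily count is divided by its own maximum; the dashed
#' line marks the event onset.
#'
#' @param object An `osn_emotion_window` tibble from [emotion_window()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.osn_emotion_window <- function(object, ...) {
  onset <- attr(object, "onset")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$norm,
                                            colour = .data$emotion)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "normalized messages", colour = "emotion") +
    ggplot2::theme_minimal()
  if (!is.null(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset, linetype = "dashed")
  }
  p
}

#' Plot topic prevalence
#'
#' Bar chart of the reported topic shares (topics under the reporting floor
#' are already excluded by [topic_prevalence()]).
#'
#' @param object An `osn_topic_prevalence` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.osn_topic_prevalence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$topic, -.data$pct),
                                       y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of messages") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
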