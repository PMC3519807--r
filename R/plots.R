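#' Compare document sources by data-containing rate and F-measure
#'
#' The headline comparison of candidate surveillance sources: how often a
#' source records true events at all, versus how precisely rule-based
#' detection works on its text.
#'
#' @param data A data frame with columns `source`, `data_containing_rate`
#'   (percent) and `f_measure` (proportion).
#' @return A ggplot object.
#' @export
plot_source_performance <- function(data) {
  data <- tibble::as_tibble(data)
  long <- data |>
    dplyr::transmute(source = .data$source,
                     `data-containing rate (%)` = .data$data_containing_rate,
                     `F-measure (x100)` = 100 * .data$f_measure) |>
    tidyr::pivot_longer(-"source", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Detection of fall events by document source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Submission-lag distributions by source
#'
#' Histograms of minutes between event occurrence and record submission,
#' one panel per source, on a log10 axis (lag distributions are strongly
#' right-skewed, often bimodal for imaging).
#'
#' @param events An event tibble (see [fall_events()]).
#' @param sources Source names to plot; defaults to all sources with any
#'   recorded event.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_lag_distribution <- function(events, sources = NULL, bins = 40) {
  if (is.null(sources)) {
    sources <- event_sources(events)
    sources <- sources[vapply(sources, function(s) {
      any(events[[paste0("recorded_", s)]])
    }, TRUE)]
  }
  long <- dplyr::bind_rows(lapply(sources, function(s) {
    sub <- events[events[[paste0("recorded_", s)]], ]
    lags <- lag_minutes(sub, s)
    tibble::tibble(source = s, lag_minutes = lags$lag_minutes)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag_minutes)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~source, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "lag from event to submission (min, log scale)",
                  y = "events",
                  title = "Submission lag by document source") +
    ggplot2::theme_minimal()
}

#' Injury-severity mix of two detection sources
#'
#' Proportional stacked bars of injury severity among events detected by
#' each of two sources (events detected by both contribute to both bars).
#'
#' @param events An event tibble.
#' @param source_a,source_b Source names.
#' @return A ggplot object.
#' @export
plot_severity_comparison <- function(events, source_a = "incident_report",
                                     source_b = "image_order") {
  long <- dplyr::bind_rows(lapply(c(source_a, source_b), function(s) {
    sub <- events[events[[paste0("recorded_", s)]], ]
    tibble::tibble(source = s, severity = as.character(sub$severity))
  }))
  long$severity <- factor(long$severity, levels = severity_levels())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source,
                                     fill = .data$severity)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of detected events",
                  fill = "injury severity",
                  title = "Injury severity by detection source") +
    ggplot2::theme_minimal()
}

#' Plot a rule set
#'
#' Positive-class support against the decision p-value of each selected
#' rule, coloured by rule size.
#'
#' @param object A `fall_ruleset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fall_ruleset <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a,
                                   y = -log10(pmax(.data$selected_p, 1e-300)),
                                   colour = factor(.data$total_terms))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "positive documents matched",
                  y = "-log10 decision p",
                  colour = "terms",
                  title = "Selected category decision rules") +
    ggplot2::theme_minimal()
}
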