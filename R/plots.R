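# ggplot2 convenience plots for the main result types.

#' Plot tweet volume over time by class
#'
#' Line chart of a [time_series()] result (one line per class), the weekly
#' view of advertising vs nonadvertising volume.
#'
#' @param ts A [time_series()] result.
#' @return A ggplot object.
#' @export
plot_time_series <- function(ts) {
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$period, y = .data$n,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "tweets", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the place-category table
#'
#' Horizontal bar chart of tweet counts per place of e-cigarette use.
#'
#' @param table A [place_table()] result.
#' @return A ggplot object.
#' @export
plot_place_table <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$n,
                                      y = stats::reorder(.data$category,
                                                         .data$n))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "tweets", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot follower trajectories of selected handles
#'
#' Follower count at time of tweet for the chosen handles; abrupt steps are
#' the visual signature burst flagging detects.
#'
#' @param corpus A corpus tibble.
#' @param handles Handles to show; defaults to the five most active.
#' @return A ggplot object.
#' @export
plot_follower_trajectories <- function(corpus, handles = NULL) {
  if (is.null(handles)) handles <- rank_handles(corpus, 5)$handle
  data <- filter(corpus, .data$handle %in% handles)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$timestamp,
                                     y = .data$follower_count,
                                     colour = .data$handle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "followers", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-fold accuracy plot for a cross-validation report
#'
#' @param object An `ad_cv_report`.
#' @param ... Unused.
#' @return A ggplot object showing fold accuracies against the
#'   majority-class baseline.
#' @method autoplot ad_cv_report
#' @export
autoplot.ad_cv_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = factor(.data$fold),
                                             y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$baseline_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
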