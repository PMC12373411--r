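# ggplot2 views of the trend tables; tabular stand-ins stay the primary output.

#' Plot group-stratified weekly metric trends
#'
#' @param object a `metric_trends` object from [metric_group_trends()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot metric_trends
#' @export
autoplot.metric_trends <- function(object, ...) {
  ggplot2::ggplot(object$weekly,
                  ggplot2::aes(x = .data$week, y = .data$mean,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "Week", y = "Weekly group mean", colour = "Group",
                  title = "Physical-activity metrics by well-being group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot weekly well-being subscale trends
#'
#' @param trends tibble from [weekly_group_trends()].
#' @return a ggplot.
#' @export
plot_wellbeing_trends <- function(trends) {
  assert_cols(trends, c("week", "group", "subscale", "mean"), "trends table")
  ggplot2::ggplot(trends, ggplot2::aes(x = .data$week, y = .data$mean,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$subscale), scales = "free_y") +
    ggplot2::labs(x = "Week", y = "Mean subscale sum", colour = "Group",
                  title = "Well-being subscales by group") +
    ggplot2::theme_minimal()
}

#' Plot weekly nutrition trends
#'
#' @param trends tibble from [aggregate_nutrition_weekly()].
#' @return a ggplot.
#' @export
plot_nutrition_trends <- function(trends) {
  assert_cols(trends, c("week", "metric", "mean"), "trends table")
  ggplot2::ggplot(trends, ggplot2::aes(x = .data$week, y = .data$mean,
                                       colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Week", y = "Cohort daily mean", colour = "Metric",
                  title = "Nutrition goal metrics over the study") +
    ggplot2::theme_minimal()
}
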