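# Weekly aggregation of daily nutrition logs and goal adherence.

nutrition_metrics <- function() c("milk_servings", "water_cups", "healthy_plate")

#' Aggregate daily nutrition logs into weekly trend summaries
#'
#' Weeks are half-open 7-day bins anchored at `study_start`
#' (week w covers days `[7(w-1), 7w)`). Records outside the `weeks * 7`-day
#' window are excluded with a warning; missing days simply do not contribute
#' to the denominator. Trend statistics are descriptive means only.
#'
#' @param logs tibble with `participant_id`, `date`, `milk_servings`,
#'   `water_cups`, `healthy_plate`.
#' @param study_start Date of study day 0.
#' @param weeks number of study weeks (default 4).
#' @return tibble with columns `week`, `metric`, `mean`, `n_records`.
#' @export
#' @examples
#' logs <- simulate_nutrition_log(demo_config(), seed = 1)
#' aggregate_nutrition_weekly(logs, study_start = as.Date("2024-01-01"))
aggregate_nutrition_weekly <- function(logs, study_start, weeks = 4) {
  assert_cols(logs, c("participant_id", "date", nutrition_metrics()),
              "nutrition log")
  if (any(logs[nutrition_metrics()] < 0, na.rm = TRUE)) {
    abort_input("nutrition quantities must be non-negative")
  }
  day <- as.integer(as.Date(logs$date) - as.Date(study_start))
  in_window <- day >= 0 & day < 7L * weeks
  if (any(!in_window)) {
    warning(sprintf("%d record(s) outside the %d-day study window were excluded",
                    sum(!in_window), 7L * weeks), call. = FALSE)
  }
  logs |>
    dplyr::mutate(week = day %/% 7L + 1L) |>
    dplyr::filter(in_window) |>
    tidyr::pivot_longer(dplyr::all_of(nutrition_metrics()),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$week, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), n_records = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$week, .data$metric)
}

#' Per-participant goal adherence
#'
#' Proportion of *logged* days on which each metric met or exceeded its daily
#' target. Days without a log are excluded from the denominator; a
#' participant-metric with no logged days yields `NA`, never zero.
#'
#' @param logs nutrition log tibble (see [aggregate_nutrition_weekly()]).
#' @param goals named numeric vector of daily targets, e.g.
#'   `c(milk_servings = 2, water_cups = 8, healthy_plate = 2)`; names must be
#'   log metrics and targets must be >= 0.
#' @return tibble with columns `participant_id`, `metric`, `adherence`
#'   (proportion in `[0, 1]` or `NA`), `n_days`.
#' @export
#' @examples
#' logs <- simulate_nutrition_log(demo_config(), seed = 1)
#' goal_adherence(logs, c(water_cups = 8))
goal_adherence <- function(logs, goals) {
  assert_cols(logs, c("participant_id", "date"), "nutrition log")
  if (is.null(names(goals)) || !all(names(goals) %in% nutrition_metrics())) {
    abort_input(sprintf("goals must be named after log metrics (%s)",
                        paste(nutrition_metrics(), collapse = ", ")))
  }
  if (any(goals < 0)) abort_input("goal targets must be >= 0")
  logs |>
    tidyr::pivot_longer(dplyr::all_of(names(goals)),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$participant_id, .data$metric) |>
    dplyr::summarise(
      adherence = mean(.data$value >= goals[[dplyr::first(.data$metric)]]),
      n_days = dplyr::n(), .groups = "drop"
    ) |>
    # participants with no logged days for a metric get NA, never zero
    tidyr::complete(participant_id = unique(logs$participant_id),
                    metric = names(goals),
                    fill = list(adherence = NA_real_, n_days = 0L)) |>
    dplyr::arrange(.data$participant_id, .data$metric)
}
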