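# Pre/post inferential layer: paired t-tests, pooled-SD Cohen's d, percent
# change, survey item summaries and group-stratified weekly metric trends.

#' Two-tailed paired t-test
#'
#' Tests the mean of the within-participant differences `pre - post` against
#' zero (so an improvement yields a negative t), with `df = n - 1` and a
#' two-sided p-value. Identical pre/post vectors (zero-variance differences)
#' are a degenerate test and raise an error rather than returning t = 0.
#'
#' @param pre,post equal-length numeric vectors, paired by participant.
#' @param item_id optional label carried into the result.
#' @return object of class `paired_ttest` with fields `t_stat`, `df`,
#'   `p_value`, `n`, `mean_diff`, `sd_diff`, `item_id`; has [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' fit <- paired_t_test(c(1, 2, 3), c(2, 2, 6))
#' tidy(fit)
paired_t_test <- function(pre, post, item_id = NULL) {
  if (length(pre) != length(post)) abort_input("pre and post must have equal lengths")
  if (length(pre) < 2) abort_input("paired t-test needs n >= 2")
  if (anyNA(pre) || anyNA(post)) abort_input("missing values: apply listwise deletion first")
  d <- pre - post
  if (stats::sd(d) == 0) {
    abort_input("degenerate paired test: all pre-post differences are identical")
  }
  ht <- stats::t.test(pre, post, paired = TRUE, alternative = "two.sided")
  structure(
    list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n = length(pre),
         mean_diff = mean(d), sd_diff = stats::sd(d), item_id = item_id),
    class = "paired_ttest"
  )
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test%s: t(%d) = %.4f, p = %.4g (n = %d, mean pre-post = %.4f)\n",
              if (is.null(x$item_id)) "" else paste0(" [", x$item_id, "]"),
              x$df, x$t_stat, x$p_value, x$n, x$mean_diff))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname paired_t_test
#' @param x a `paired_ttest` object.
#' @param ... unused.
#' @method tidy paired_ttest
#' @export
tidy.paired_ttest <- function(x, ...) {
  tibble::tibble(item_id = x$item_id %||% NA_character_,
                 estimate = x$mean_diff, statistic = x$t_stat,
                 df = x$df, p.value = x$p_value)
}

#' @rdname paired_t_test
#' @method glance paired_ttest
#' @export
glance.paired_ttest <- function(x, ...) {
  tibble::tibble(n = x$n, statistic = x$t_stat, df = x$df,
                 p.value = x$p_value, sd_diff = x$sd_diff)
}

#' Pooled-SD Cohen's d
#'
#' Standardized mean difference
#' `d = (post_mean - pre_mean) / sqrt((pre_sd^2 + post_sd^2) / 2)`.
#' The sign follows the direction of change (positive = increase); report
#' layers print the magnitude rounded to 2 decimals.
#'
#' @param pre_mean,pre_sd,post_mean,post_sd summary moments (SDs >= 0, not
#'   both zero).
#' @return signed effect size (vectorized).
#' @export
#' @examples
#' cohens_d_pooled(3.18, 0.79, 3.95, 0.82) # ~0.96
cohens_d_pooled <- function(pre_mean, pre_sd, post_mean, post_sd) {
  if (any(pre_sd < 0) || any(post_sd < 0)) abort_input("standard deviations must be >= 0")
  pooled <- sqrt((pre_sd^2 + post_sd^2) / 2)
  if (any(pooled == 0)) abort_input("degenerate effect size: both standard deviations are zero")
  (post_mean - pre_mean) / pooled
}

#' Percent change
#'
#' `100 * (after - before) / before`; undefined for `before = 0`. Reports
#' round half away from zero via `digits`.
#'
#' @param before,after numeric values (`before != 0`).
#' @param digits if non-NULL, round half-away-from-zero to this many decimals.
#' @return percent change (vectorized).
#' @export
#' @examples
#' percent_change(18.7, 19.1, digits = 2) # 2.14
percent_change <- function(before, after, digits = NULL) {
  if (any(before == 0)) abort_input("percent change is undefined for before = 0")
  pc <- 100 * (after - before) / before
  if (is.null(digits)) pc else round_half_out(pc, digits)
}

#' Summarize paired survey items
#'
#' One row per item: sample size after listwise deletion, pre/post means and
#' sample SDs (n - 1 denominator), paired t statistic with `df = n - 1`,
#' two-sided p, and signed pooled-SD Cohen's d. Items with fewer than two
#' complete pairs are skipped with a warning; items whose differences have
#' zero variance get `NA` for t and p with a warning (the effect size is
#' still computed when defined).
#'
#' @param survey tibble with columns `participant_id`, `item_id`,
#'   `pre_value`, `post_value` (one row per participant-item).
#' @param items optional character vector restricting/ordering the items.
#' @return tibble with columns `item_id`, `n`, `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`, `t_stat`, `df`, `p_value`, `cohens_d`.
#' @export
#' @examples
#' sv <- simulate_survey_prepost(demo_config(), seed = 1)
#' summarize_items(sv)
summarize_items <- function(survey, items = NULL) {
  assert_cols(survey, c("participant_id", "item_id", "pre_value", "post_value"),
              "survey table")
  items <- items %||% sort(unique(survey$item_id))
  rows <- purrr::map(items, function(it) {
    d <- dplyr::filter(survey, .data$item_id == it,
                       !is.na(.data$pre_value), !is.na(.data$post_value))
    n_dropped <- sum(survey$item_id == it) - nrow(d)
    if (n_dropped > 0) {
      message(sprintf("item %s: %d incomplete pair(s) dropped", it, n_dropped))
    }
    if (nrow(d) < 2) {
      warning(sprintf("item %s skipped: fewer than 2 complete pairs", it),
              call. = FALSE)
      return(NULL)
    }
    fit <- tryCatch(paired_t_test(d$pre_value, d$post_value, item_id = it),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("item %s: degenerate paired test (zero-variance differences)", it),
              call. = FALSE)
    }
    dd <- tryCatch(
      cohens_d_pooled(mean(d$pre_value), stats::sd(d$pre_value),
                      mean(d$post_value), stats::sd(d$post_value)),
      error = function(e) NA_real_
    )
    tibble::tibble(
      item_id = it, n = nrow(d),
      pre_mean = mean(d$pre_value), pre_sd = stats::sd(d$pre_value),
      post_mean = mean(d$post_value), post_sd = stats::sd(d$post_value),
      t_stat = if (is.null(fit)) NA_real_ else fit$t_stat,
      df = nrow(d) - 1L,
      p_value = if (is.null(fit)) NA_real_ else fit$p_value,
      cohens_d = dd
    )
  })
  dplyr::bind_rows(rows)
}

#' Group-stratified weekly metric trends
#'
#' Weekly group means of the aggregate session metrics (action count, maximum
#' acceleration, RMS acceleration, energy) plus the first-to-last-week percent
#' change per group per metric. Weekly values are means over that week's
#' segments.
#'
#' @param metrics output of [compute_segment_metrics()] (the `AGGREGATE` rows
#'   are used when present, otherwise all rows).
#' @param classifications tibble `participant_id`, `classification` (e.g.
#'   from [participant_classification()]). Every participant in `metrics`
#'   must be classified.
#' @return object of class `metric_trends`: a list with `weekly` (tibble
#'   `week`, `group`, `metric`, `mean`, `n`) and `change` (tibble `group`,
#'   `metric`, `first_week_mean`, `last_week_mean`, `percent_change`,
#'   rounded to 2 decimals); has a [tidy()] method returning `weekly`.
#' @export
#' @examples
#' cfg <- demo_config()
#' sensors <- simulate_imu_session(cfg, "P01", 1, "fruit_ninja", seed = 1)
#' m <- compute_segment_metrics(sensors)
#' cls <- tibble::tibble(participant_id = "P01", classification = "mentally_well")
#' metric_group_trends(m, cls)$weekly
metric_group_trends <- function(metrics, classifications) {
  assert_cols(metrics, c("participant_id", "week", "action_count", "max_acc",
                         "rms_acc", "energy_kcal"), "metrics table")
  assert_cols(classifications, c("participant_id", "classification"),
              "classification table")
  if ("sensor_site" %in% names(metrics) && any(metrics$sensor_site == "AGGREGATE")) {
    metrics <- dplyr::filter(metrics, .data$sensor_site == "AGGREGATE")
  }
  missing <- setdiff(unique(metrics$participant_id),
                     classifications$participant_id)
  if (length(missing) > 0) {
    abort_input(paste0("unclassified participant(s): ",
                       paste(sort(missing), collapse = ", ")))
  }
  joined <- dplyr::inner_join(metrics,
                              dplyr::distinct(classifications, .data$participant_id,
                                              .data$classification),
                              by = "participant_id")
  weekly <- joined |>
    tidyr::pivot_longer(c("action_count", "max_acc", "rms_acc", "energy_kcal"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(week = .data$week, group = .data$classification,
                    metric = .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$week, .data$group, .data$metric)
  change <- weekly |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      first_week_mean = .data$mean[which.min(.data$week)],
      last_week_mean = .data$mean[which.max(.data$week)],
      .groups = "drop"
    ) |>
    dplyr::mutate(percent_change = percent_change(.data$first_week_mean,
                                                  .data$last_week_mean,
                                                  digits = 2))
  structure(list(weekly = weekly, change = change), class = "metric_trends")
}

#' @export
print.metric_trends <- function(x, ...) {
  cat("<metric_trends>\n$weekly:\n")
  print(x$weekly, n = 8)
  cat("$change:\n")
  print(x$change)
  invisible(x)
}

#' @rdname metric_group_trends
#' @param x a `metric_trends` object.
#' @param ... unused.
#' @method tidy metric_trends
#' @export
tidy.metric_trends <- function(x, ...) x$weekly

#' @rdname metric_group_trends
#' @method glance metric_trends
#' @export
glance.metric_trends <- function(x, ...) {
  tidyr::pivot_wider(dplyr::select(x$change, "group", "metric", "percent_change"),
                     names_from = "metric", values_from = "percent_change")
}
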