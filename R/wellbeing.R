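# MHC-SF scoring, mentally-well/moderate classification, weekly group trends.

mhcsf_item_cols <- function() sprintf("item_%02d", 1:14)

#' Subscale item mapping for the 14-item MHC-SF adaptation
#'
#' Standard structure: items 1-3 emotional (hedonic), 4-8 social, 9-14
#' psychological; eudemonic = social + psychological (items 4-14). The
#' mapping is configuration, not code, so an adapted instrument with a
#' different ordering can be scored by supplying its own mapping.
#'
#' @param emotional,social,psychological integer item positions (1-14).
#' @return named list of index vectors.
#' @export
mhcsf_subscales <- function(emotional = 1:3, social = 4:8, psychological = 9:14) {
  idx <- c(emotional, social, psychological)
  if (!setequal(idx, 1:14) || length(idx) != 14) {
    abort_input("subscales must partition items 1..14")
  }
  list(emotional = emotional, social = social, psychological = psychological)
}

validate_mhcsf <- function(responses) {
  assert_cols(responses, c("participant_id", "week", mhcsf_item_cols()),
              "MHC-SF table")
  items <- as.matrix(responses[mhcsf_item_cols()])
  if (anyNA(items)) abort_input("MHC-SF responses contain missing items; no imputation is performed")
  if (any(items != round(items)) || any(items < 0) || any(items > 5)) {
    abort_input("MHC-SF items must be integer frequency codes in 0..5")
  }
  items
}

#' Score MHC-SF responses into subscale sums
#'
#' Sums the raw frequency codes (0-5) within each subscale: emotional 0-15,
#' social 0-25, psychological 0-30.
#'
#' @param responses tibble with `participant_id`, `week`,
#'   `item_01` ... `item_14`.
#' @param subscales mapping from [mhcsf_subscales()].
#' @return the input with `emotional`, `social`, `psychological` columns
#'   appended.
#' @export
#' @examples
#' r <- tibble::tibble(participant_id = "P01", week = 1,
#'                     !!!stats::setNames(as.list(rep(5, 14)), sprintf("item_%02d", 1:14)))
#' score_mhcsf(r)[, c("emotional", "social", "psychological")]
score_mhcsf <- function(responses, subscales = mhcsf_subscales()) {
  items <- validate_mhcsf(responses)
  dplyr::mutate(
    responses,
    emotional = rowSums(items[, subscales$emotional, drop = FALSE]),
    social = rowSums(items[, subscales$social, drop = FALSE]),
    psychological = rowSums(items[, subscales$psychological, drop = FALSE])
  )
}

#' Classify responses as mentally well or moderate
#'
#' A response is `mentally_well` when at least 1 of the 3 hedonic items and
#' at least 6 of the 11 eudemonic items were experienced "every day" or
#' "5-6 times a week" (frequency code >= 4); otherwise `moderate`. The
#' dichotomy is deliberate: the analysis compares exactly these two groups.
#'
#' @inheritParams score_mhcsf
#' @param threshold minimum frequency code counting as a "sign" (default 4).
#' @return the input with a `classification` column
#'   (`"mentally_well"`/`"moderate"`).
#' @export
classify_mental_health <- function(responses, subscales = mhcsf_subscales(),
                                   threshold = 4) {
  items <- validate_mhcsf(responses)
  hed <- rowSums(items[, subscales$emotional, drop = FALSE] >= threshold)
  eud_idx <- sort(c(subscales$social, subscales$psychological))
  eud <- rowSums(items[, eud_idx, drop = FALSE] >= threshold)
  dplyr::mutate(responses,
                classification = ifelse(hed >= 1 & eud >= 6,
                                        "mentally_well", "moderate"))
}

#' Participant-level classification table
#'
#' One classification per participant, either from the week-1 response
#' (default; the stratification must stay fixed to compare groups over time)
#' or separately per week.
#'
#' @inheritParams classify_mental_health
#' @param basis `"week1"` (default) or `"per_week"`.
#' @return tibble `participant_id` (+ `week` when per-week), `classification`.
#' @export
participant_classification <- function(responses, basis = c("week1", "per_week"),
                                       subscales = mhcsf_subscales(),
                                       threshold = 4) {
  basis <- match.arg(basis)
  cls <- classify_mental_health(responses, subscales, threshold)
  if (basis == "week1") {
    cls |>
      dplyr::filter(.data$week == min(.data$week)) |>
      dplyr::select("participant_id", "classification")
  } else {
    dplyr::select(cls, "participant_id", "week", "classification")
  }
}

#' Weekly group-stratified well-being trends
#'
#' Mean subscale sums per week per classification group. Empty (week, group)
#' cells are absent from the table rather than reported as zero.
#'
#' @inheritParams classify_mental_health
#' @param basis `"week1"`: classify from the week-1 response and hold the
#'   group fixed; `"per_week"`: reclassify each week.
#' @return tibble with columns `week`, `group`, `subscale`, `mean`, `n`.
#' @export
#' @examples
#' resp <- simulate_mhcsf_weekly(demo_config(), seed = 1)
#' weekly_group_trends(resp)
weekly_group_trends <- function(responses, basis = c("week1", "per_week"),
                                subscales = mhcsf_subscales(), threshold = 4) {
  basis <- match.arg(basis)
  scored <- score_mhcsf(responses, subscales)
  cls <- participant_classification(responses, basis, subscales, threshold)
  joined <- if (basis == "week1") {
    dplyr::inner_join(scored, cls, by = "participant_id")
  } else {
    dplyr::inner_join(scored, cls, by = c("participant_id", "week"))
  }
  joined |>
    tidyr::pivot_longer(c("emotional", "social", "psychological"),
                        names_to = "subscale", values_to = "score") |>
    dplyr::group_by(week = .data$week, group = .data$classification,
                    subscale = .data$subscale) |>
    dplyr::summarise(mean = mean(.data$score), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$week, .data$group, .data$subscale)
}
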