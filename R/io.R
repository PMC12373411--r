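# CSV dialects shared by the simulator and the ingestion path.

#' Read study input CSVs
#'
#' Readers for the four input dialects, with schema validation:
#' * sensors: `participant_id,week,game,sensor_site,t,ax,ay,az[,gx,gy,gz]`
#' * MHC-SF: `participant_id,week,item_01..item_14` (codes 0-5)
#' * survey: `participant_id,item_id,phase{pre|post},value` (long), returned
#'   wide with `pre_value`/`post_value`
#' * nutrition: `participant_id,date,milk_servings,water_cups,healthy_plate`
#'
#' @param path CSV file path.
#' @return a validated tibble.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_sensor_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("participant_id", "week", "game", "sensor_site",
                   "t", "ax", "ay", "az"), path)
  bad <- setdiff(unique(x$sensor_site), sensor_sites())
  if (length(bad) > 0) {
    abort_input(sprintf("%s: unknown sensor_site value(s): %s",
                        path, paste(bad, collapse = ", ")))
  }
  x
}

#' @rdname read_inputs
#' @export
read_mhcsf_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_mhcsf(x)
  x
}

#' @rdname read_inputs
#' @export
read_survey_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("participant_id", "item_id", "phase", "value"), path)
  if (!all(x$phase %in% c("pre", "post"))) {
    abort_input(sprintf("%s: phase must be 'pre' or 'post'", path))
  }
  tidyr::pivot_wider(x, id_cols = c("participant_id", "item_id"),
                     names_from = "phase", values_from = "value",
                     names_glue = "{phase}_value")
}

#' @rdname read_inputs
#' @export
read_nutrition_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(x, c("participant_id", "date", nutrition_metrics()), path)
  x
}

#' Write a paired survey table in the long CSV dialect
#'
#' @param survey tibble with `participant_id`, `item_id`, `pre_value`,
#'   `post_value`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  long <- survey |>
    dplyr::select("participant_id", "item_id", "pre_value", "post_value") |>
    tidyr::pivot_longer(c("pre_value", "post_value"),
                        names_to = "phase", values_to = "value") |>
    dplyr::mutate(phase = sub("_value$", "", .data$phase)) |>
    dplyr::arrange(.data$item_id, .data$participant_id,
                   dplyr::desc(.data$phase))
  readr::write_csv(long, path)
  invisible(path)
}
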