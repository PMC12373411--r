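#' Published pre/post survey summary moments
#'
#' Pre- and post-intervention means and standard deviations (n = 30 paired
#' completers) for the seven technology-acceptance / self-rated-health Likert
#' items of the evaluation cohort. Shipped as a plain-text table; used both as
#' the default `survey_item_params` of [cohort_config()] and as the input for
#' recomputing pooled-SD effect sizes.
#'
#' @return A tibble with columns `item_id`, `label`, `n`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd`.
#' @export
#' @examples
#' survey_item_moments()
survey_item_moments <- function() {
  path <- system.file("extdata", "survey_item_moments.csv", package = "kinewell")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Default per-item survey simulation parameters
#'
#' The published item moments augmented with the simulation-only fields: the
#' pre/post within-subject correlation and the Likert response bounds.
#'
#' @param paired_correlation within-subject pre/post correlation (default 0.5).
#' @param scale_min,scale_max Likert bounds applied to every item (default 1-5);
#'   override per item by editing the returned tibble.
#' @return tibble with one row per item.
#' @export
default_survey_item_params <- function(paired_correlation = 0.5,
                                       scale_min = 1, scale_max = 5) {
  moments <- survey_item_moments()
  dplyr::mutate(
    dplyr::select(moments, "item_id", "pre_mean", "pre_sd", "post_mean", "post_sd"),
    paired_correlation = paired_correlation,
    scale_min = scale_min,
    scale_max = scale_max
  )
}

#' Default MHC-SF response profiles for the two well-being groups
#'
#' Category probabilities (frequency codes 0 = never ... 5 = every day) used by
#' the weekly questionnaire simulator. The "well" profile concentrates mass on
#' the top two categories so that simulated flourishing participants satisfy
#' the mentally-well rule with high probability; the "moderate" profile
#' concentrates on mid categories. One probability vector is applied to all 14
#' items of a group; supply a 14 x 6 matrix per group for per-item control.
#'
#' @return named list with elements `well` and `moderate`, each a probability
#'   vector of length 6 (categories 0-5) or a 14 x 6 matrix.
#' @export
default_mhcsf_profile <- function() {
  list(
    well     = c(0.01, 0.02, 0.05, 0.12, 0.35, 0.45),
    moderate = c(0.10, 0.20, 0.30, 0.25, 0.10, 0.05)
  )
}

#' Default weekly drift parameters for the nutrition simulator
#'
#' Baseline daily value, additive per-week drift, and day-to-day noise SD for
#' each logged metric. Defaults mirror the qualitative trends of the study:
#' steady milk intake, gradually rising water consumption, and a substantial
#' rise in balanced-plate entries.
#'
#' @return named list of `c(base, drift, noise_sd)` per metric.
#' @export
default_nutrition_trend <- function() {
  list(
    milk_servings = c(base = 1.5, drift = 0.0, noise_sd = 0.5),
    water_cups    = c(base = 6.0, drift = 0.5, noise_sd = 1.0),
    healthy_plate = c(base = 1.0, drift = 0.3, noise_sd = 0.8)
  )
}

#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the study design
#' (participants, arms, weeks, games, sensor layout), the IMU signal model,
#' the paired pre/post survey model, the weekly MHC-SF response profiles and
#' the nutrition drift model. Defaults encode the published study design:
#' 48 participants in 4 arms, 30 survey completers, 4 weekly sessions of
#' 3 exergames at 10 minutes each, and 5 body-worn sensors.
#'
#' @param n_participants cohort size (default 48).
#' @param n_survey_completers participants with both pre and post surveys
#'   (default 30); must not exceed `n_participants`.
#' @param arms study-arm labels (4 by default).
#' @param weeks number of weekly sessions (default 4).
#' @param games exergame labels (default 3).
#' @param segment_duration_s duration of one game segment in seconds
#'   (default 600 = 10 min).
#' @param sampling_hz IMU sampling rate in samples/second (default 50; the
#'   device rate is configurable because it is deployment-specific).
#' @param seed default base seed used when a simulator is called without one.
#' @param peak_rate_hz expected movement-burst rate per second (Poisson,
#'   default 0.5).
#' @param peak_amplitude mean burst magnitude in m/s^2 added along the gravity
#'   axis (default 6).
#' @param baseline_noise_sd per-axis Gaussian sensor noise SD in m/s^2
#'   (default 0.3).
#' @param include_gravity logical; add +g (9.80665 m/s^2) to the vertical axis
#'   so magnitudes are raw, gravity-inclusive (default TRUE).
#' @param amplitude_jitter_sdlog lognormal SD of per-burst amplitude jitter
#'   (default 0.15; 0 disables).
#' @param site_scale named multipliers of burst amplitude per sensor site.
#' @param survey_item_params tibble as [default_survey_item_params()].
#' @param mhcsf_profile list as [default_mhcsf_profile()].
#' @param p_mentally_well probability a simulated participant belongs to the
#'   flourishing ("well") profile (default 0.5).
#' @param nutrition_trend list as [default_nutrition_trend()].
#' @param study_start first study day (Date; anchors nutrition weeks).
#' @param weight_mean_kg,weight_sd_kg body-mass distribution used to draw
#'   per-participant weights (clamped to 45-95 kg).
#' @return an object of class `cohort_config` (a validated named list).
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 6, n_survey_completers = 4)
#' cfg$sampling_hz
cohort_config <- function(n_participants = 48,
                          n_survey_completers = 30,
                          arms = c("conventional_exercise", "exergame_only",
                                   "exergame_coach", "exergame_peer"),
                          weeks = 4,
                          games = c("fruit_ninja", "piano_step", "arctic_punch"),
                          segment_duration_s = 600,
                          sampling_hz = 50,
                          seed = 20250822L,
                          peak_rate_hz = 0.5,
                          peak_amplitude = 6,
                          baseline_noise_sd = 0.3,
                          include_gravity = TRUE,
                          amplitude_jitter_sdlog = 0.15,
                          site_scale = c(forearm_L = 1, forearm_R = 1,
                                         waist_L4 = 0.6, foot_L = 0.8, foot_R = 0.8),
                          survey_item_params = default_survey_item_params(),
                          mhcsf_profile = default_mhcsf_profile(),
                          p_mentally_well = 0.5,
                          nutrition_trend = default_nutrition_trend(),
                          study_start = as.Date("2024-01-01"),
                          weight_mean_kg = 68,
                          weight_sd_kg = 11) {
  cfg <- structure(
    list(
      n_participants = as.integer(n_participants),
      n_survey_completers = as.integer(n_survey_completers),
      arms = arms, weeks = as.integer(weeks), games = games,
      segment_duration_s = segment_duration_s, sampling_hz = sampling_hz,
      seed = as.integer(seed),
      peak_rate_hz = peak_rate_hz, peak_amplitude = peak_amplitude,
      baseline_noise_sd = baseline_noise_sd, include_gravity = include_gravity,
      amplitude_jitter_sdlog = amplitude_jitter_sdlog,
      site_scale = site_scale,
      survey_item_params = survey_item_params,
      mhcsf_profile = mhcsf_profile,
      p_mentally_well = p_mentally_well,
      nutrition_trend = nutrition_trend,
      study_start = as.Date(study_start),
      weight_mean_kg = weight_mean_kg, weight_sd_kg = weight_sd_kg
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

sensor_sites <- function() c("forearm_L", "forearm_R", "waist_L4", "foot_L", "foot_R")

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) abort_input("n_participants must be >= 1")
  if (cfg$n_survey_completers > cfg$n_participants) {
    abort_input("n_survey_completers must not exceed n_participants")
  }
  if (cfg$sampling_hz <= 0) abort_input("sampling_hz must be > 0")
  if (cfg$segment_duration_s <= 0) abort_input("segment_duration_s must be > 0")
  if (cfg$peak_rate_hz < 0) abort_input("peak_rate_hz must be >= 0")
  if (cfg$baseline_noise_sd < 0) abort_input("baseline_noise_sd must be >= 0")
  if (cfg$peak_amplitude < 0) abort_input("peak_amplitude must be >= 0")
  if (!setequal(names(cfg$site_scale), sensor_sites())) {
    abort_input(sprintf("site_scale must name exactly the five sensor sites: %s",
                        paste(sensor_sites(), collapse = ", ")))
  }
  sp <- cfg$survey_item_params
  assert_cols(sp, c("item_id", "pre_mean", "pre_sd", "post_mean", "post_sd",
                    "paired_correlation", "scale_min", "scale_max"),
              "survey_item_params")
  if (any(abs(sp$paired_correlation) > 1)) {
    abort_input("survey_item_params: |paired_correlation| must be <= 1")
  }
  if (any(sp$scale_min >= sp$scale_max)) {
    abort_input("survey_item_params: scale_min must be < scale_max for every item")
  }
  for (grp in c("well", "moderate")) {
    pr <- cfg$mhcsf_profile[[grp]]
    if (is.null(pr)) abort_input(sprintf("mhcsf_profile must contain a '%s' element", grp))
    pm <- if (is.matrix(pr)) pr else matrix(pr, nrow = 14, ncol = 6, byrow = TRUE)
    if (ncol(pm) != 6 || nrow(pm) != 14) {
      abort_input("mhcsf_profile entries must be length-6 vectors or 14 x 6 matrices")
    }
    if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9)) {
      abort_input(sprintf("mhcsf_profile '%s': category probabilities must be >= 0 and sum to 1", grp))
    }
  }
  for (m in names(cfg$nutrition_trend)) {
    p <- cfg$nutrition_trend[[m]]
    if (p[["base"]] < 0 || p[["noise_sd"]] < 0) {
      abort_input(sprintf("nutrition_trend '%s': base and noise_sd must be >= 0", m))
    }
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  participants: %d (%d survey completers), arms: %d, weeks: %d\n",
              x$n_participants, x$n_survey_completers, length(x$arms), x$weeks))
  cat(sprintf("  games: %s\n", paste(x$games, collapse = ", ")))
  cat(sprintf("  IMU: %d s @ %g Hz, burst rate %g Hz, amplitude %g m/s^2, noise sd %g\n",
              x$segment_duration_s, x$sampling_hz, x$peak_rate_hz,
              x$peak_amplitude, x$baseline_noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Small demonstration configuration
#'
#' A scaled-down cohort (6 participants, 30 s segments at 25 Hz) used by the
#' end-to-end pipeline examples and the determinism tests; every downstream
#' stage behaves identically to the full-size design, only problem sizes shrink.
#'
#' @param ... overrides passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
demo_config <- function(...) {
  cohort_config(n_participants = 6, n_survey_completers = 4,
                segment_duration_s = 30, sampling_hz = 25, ...)
}

#' Read a cohort configuration from YAML or JSON
#'
#' Scalar fields of the document override [cohort_config()] defaults; the
#' `survey_item_params` field, if present, must be a record list convertible
#' to a data frame.
#'
#' @param path file path ending in .yaml/.yml or .json.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file not found: %s", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(doc$survey_item_params)) {
    doc$survey_item_params <- tibble::as_tibble(doc$survey_item_params)
  }
  if (!is.null(doc$site_scale)) doc$site_scale <- unlist(doc$site_scale)
  if (!is.null(doc$nutrition_trend)) {
    doc$nutrition_trend <- lapply(doc$nutrition_trend, unlist)
  }
  do.call(cohort_config, doc)
}
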