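small_cfg <- function(...) {
  cohort_config(n_participants = 4, n_survey_completers = 3,
                segment_duration_s = 20, sampling_hz = 25, ...)
}

test_that("config validation rejects inconsistent designs", {
  expect_error(cohort_config(n_participants = 10, n_survey_completers = 11),
               "n_survey_completers")
  expect_error(small_cfg(sampling_hz = 0), "sampling_hz")
  expect_error(small_cfg(segment_duration_s = -1), "segment_duration_s")
  expect_error(small_cfg(peak_rate_hz = -0.1), "peak_rate_hz")
  expect_error(small_cfg(mhcsf_profile = list(well = rep(0.2, 6),
                                              moderate = rep(0.1, 6))),
               "sum to 1")
  bad_survey <- default_survey_item_params()
  bad_survey$paired_correlation <- 1.5
  expect_error(small_cfg(survey_item_params = bad_survey), "paired_correlation")
  bad_scale <- default_survey_item_params(scale_min = 5, scale_max = 5)
  expect_error(small_cfg(survey_item_params = bad_scale), "scale_min")
  expect_error(small_cfg(site_scale = c(hand = 1)), "sensor sites")
})

test_that("a YAML config round-trips through read_cohort_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_participants: 5", "n_survey_completers: 2",
               "sampling_hz: 20", "segment_duration_s: 15"), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_participants, 5L)
  expect_equal(cfg$sampling_hz, 20)
  expect_error(read_cohort_config(tempfile()), "not found")
})

test_that("IMU sessions have the configured geometry", {
  cfg <- cohort_config(n_participants = 2, n_survey_completers = 2)
  fr <- simulate_imu_session(cfg, "P01", 1, "fruit_ninja", seed = 5)
  counts <- dplyr::count(fr, sensor_site)
  expect_setequal(counts$sensor_site,
                  c("forearm_L", "forearm_R", "waist_L4", "foot_L", "foot_R"))
  expect_true(all(counts$n == 600 * 50)) # 600 s at 50 Hz -> 30,000 samples
  # timestamps strictly increasing and uniform within each frame
  one <- fr[fr$sensor_site == "waist_L4", ]
  expect_true(all(diff(one$t) > 0))
  expect_equal(max(abs(diff(one$t) - 1 / 50)), 0, tolerance = 1e-12)
})

test_that("simulators are bit-reproducible under a fixed seed", {
  cfg <- small_cfg()
  expect_identical(simulate_imu_session(cfg, "P01", 2, "piano_step", seed = 9),
                   simulate_imu_session(cfg, "P01", 2, "piano_step", seed = 9))
  expect_identical(simulate_survey_prepost(cfg, seed = 9),
                   simulate_survey_prepost(cfg, seed = 9))
  expect_identical(simulate_mhcsf_weekly(cfg, seed = 9),
                   simulate_mhcsf_weekly(cfg, seed = 9))
  expect_identical(simulate_nutrition_log(cfg, seed = 9),
                   simulate_nutrition_log(cfg, seed = 9))
  # and sensitive to the seed
  expect_false(identical(simulate_survey_prepost(cfg, seed = 9),
                         simulate_survey_prepost(cfg, seed = 10)))
})

test_that("detected peak counts track the generator's Poisson event log", {
  cfg <- cohort_config(n_participants = 2, n_survey_completers = 2)
  fr <- simulate_imu_session(cfg, "P01", 1, "arctic_punch", seed = 101)
  true_events <- nrow(attr(fr, "events"))
  d <- fr[fr$sensor_site == "forearm_L", ]
  peaks <- detect_peaks(accel_magnitude(d$ax, d$ay, d$az), fs = cfg$sampling_hz)
  # default detection settings: count within 3 sigma of the Poisson mean 300
  lambda <- cfg$peak_rate_hz * cfg$segment_duration_s
  expect_equal(lambda, 300)
  expect_gt(length(peaks), lambda - 3 * sqrt(lambda))
  expect_lt(length(peaks), lambda + 3 * sqrt(lambda))
  expect_gt(true_events, lambda - 3 * sqrt(lambda))
  expect_lt(true_events, lambda + 3 * sqrt(lambda))
})

test_that("survey moments and pairing structure are recovered", {
  params <- tibble::tibble(item_id = "Q3", pre_mean = 3.18, pre_sd = 0.79,
                           post_mean = 3.95, post_sd = 0.82,
                           paired_correlation = 0.5, scale_min = 1, scale_max = 5)
  cfg <- cohort_config(n_participants = 10000, n_survey_completers = 10000,
                       survey_item_params = params)
  sv <- simulate_survey_prepost(cfg, seed = 3)
  expect_equal(nrow(sv), 10000)
  # law of large numbers on the pre-clipping (latent) scale
  expect_equal(mean(sv$pre_latent), 3.18, tolerance = 0.05 / 3.18)
  expect_equal(stats::sd(sv$pre_latent), 0.79, tolerance = 0.03)
  expect_equal(stats::cor(sv$pre_latent, sv$post_latent), 0.5, tolerance = 0.05)
  # discretized responses live on the Likert scale
  expect_true(all(sv$pre_value %in% 1:5 & sv$post_value %in% 1:5))
})

test_that("perfect correlation with equal moments makes pre equal post pre-discretization", {
  params <- tibble::tibble(item_id = "Q1", pre_mean = 3, pre_sd = 0.8,
                           post_mean = 3, post_sd = 0.8,
                           paired_correlation = 1, scale_min = 1, scale_max = 5)
  cfg <- cohort_config(n_participants = 50, n_survey_completers = 50,
                       survey_item_params = params)
  sv <- simulate_survey_prepost(cfg, seed = 4)
  expect_equal(sv$pre_latent, sv$post_latent)
})

test_that("the default design yields 30 paired rows per item", {
  cfg <- cohort_config(segment_duration_s = 10, sampling_hz = 10)
  sv <- simulate_survey_prepost(cfg, seed = 2)
  expect_equal(as.vector(table(sv$item_id)), rep(30L, 7))
})

test_that("MHC-SF point-mass profiles force the classification", {
  top <- c(0, 0, 0, 0, 0, 1)
  bottom <- c(1, 0, 0, 0, 0, 0)
  cfg_top <- small_cfg(mhcsf_profile = list(well = top, moderate = top))
  cfg_bot <- small_cfg(mhcsf_profile = list(well = bottom, moderate = bottom))
  all_top <- classify_mental_health(simulate_mhcsf_weekly(cfg_top, seed = 6))
  all_bot <- classify_mental_health(simulate_mhcsf_weekly(cfg_bot, seed = 6))
  expect_true(all(all_top$classification == "mentally_well"))
  expect_true(all(all_bot$classification == "moderate"))
})

test_that("classified proportion matches the generator's latent labels", {
  cfg <- cohort_config(n_participants = 400, n_survey_completers = 30,
                       weeks = 1, p_mentally_well = 0.5)
  roster <- simulate_cohort_roster(cfg, seed = 8)
  resp <- simulate_mhcsf_weekly(cfg, roster, seed = 8)
  cls <- participant_classification(resp)
  joined <- dplyr::inner_join(cls, roster, by = "participant_id")
  accuracy <- mean((joined$classification == "mentally_well") ==
                     (joined$true_group == "well"))
  # default profiles classify their own group with >= 95% probability, so
  # agreement should be far above the 3-sigma binomial floor around 0.95
  expect_gt(accuracy, 0.95 - 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("nutrition logs reproduce the configured drift and record count", {
  flat <- small_cfg(nutrition_trend = list(
    milk_servings = c(base = 2, drift = 0, noise_sd = 0),
    water_cups = c(base = 6, drift = 0, noise_sd = 0),
    healthy_plate = c(base = 1, drift = 0, noise_sd = 0)))
  logs <- simulate_nutrition_log(flat, seed = 5)
  expect_true(all(logs$milk_servings == 2))
  expect_true(all(logs$water_cups == 6))
  expect_true(all(logs$healthy_plate == 1))

  cfg <- cohort_config(n_participants = 300, n_survey_completers = 30,
                       nutrition_trend = list(
                         milk_servings = c(base = 2, drift = 0, noise_sd = 0.5),
                         water_cups = c(base = 6, drift = 0.5, noise_sd = 1),
                         healthy_plate = c(base = 1, drift = 0.3, noise_sd = 0.8)))
  logs <- simulate_nutrition_log(cfg, seed = 5)
  expect_equal(nrow(logs), 300 * 28)
  wk <- aggregate_nutrition_weekly(logs, cfg$study_start)
  water <- wk[wk$metric == "water_cups", ]
  expect_equal(water$mean[water$week == 4] - water$mean[water$week == 1],
               1.5, tolerance = 0.1)
  expect_error(small_cfg(nutrition_trend = list(
    milk_servings = c(base = -1, drift = 0, noise_sd = 0))), "non|>= 0")
})

test_that("the default cohort size gives 1,344 nutrition records", {
  cfg <- cohort_config(segment_duration_s = 10, sampling_hz = 10)
  logs <- simulate_nutrition_log(cfg, seed = 1)
  expect_equal(nrow(logs), 48 * 28)
})
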