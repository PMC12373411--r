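# Seeded synthetic cohort generators. Every simulator is bit-reproducible for
# a given (config, seed): per-cell RNG streams are derived from (seed, ids) so
# results do not depend on call order.

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate the cohort roster
#'
#' Draws the fixed per-participant attributes: study arm (balanced random
#' allocation), body mass, the latent well-being group driving the MHC-SF
#' simulator, and whether the participant completed both surveys. The latent
#' group label is ground truth for oracle-based tests and is not visible to
#' the analysis stages, which classify from simulated questionnaires.
#'
#' @param config a [cohort_config()].
#' @param seed base seed; defaults to `config$seed`.
#' @return tibble with columns `participant_id`, `arm`, `weight_kg`,
#'   `true_group` (`well`/`moderate`), `survey_completer` (logical).
#' @export
#' @examples
#' simulate_cohort_roster(demo_config(), seed = 1)
simulate_cohort_roster <- function(config, seed = config$seed) {
  n <- config$n_participants
  withr::with_seed(derive_seed(seed, "roster"), {
    arm <- sample(rep_len(config$arms, n))
    weight <- pmin(95, pmax(45, stats::rnorm(n, config$weight_mean_kg, config$weight_sd_kg)))
    grp <- ifelse(stats::runif(n) < config$p_mentally_well, "well", "moderate")
    completer <- seq_len(n) %in% sample.int(n, config$n_survey_completers)
  })
  tibble::tibble(
    participant_id = participant_ids(n),
    arm = arm,
    weight_kg = round(weight, 1),
    true_group = grp,
    survey_completer = completer
  )
}

# half-sine acceleration pulse of `width_s` seconds added at each event time
add_bursts <- function(signal, t, events, amplitudes, width_s = 0.3) {
  for (k in seq_along(events)) {
    idx <- which(t >= events[k] & t <= events[k] + width_s)
    if (length(idx) > 0) {
      signal[idx] <- signal[idx] +
        amplitudes[k] * sin(pi * (t[idx] - events[k]) / width_s)
    }
  }
  signal
}

#' Simulate one IMU session (all five sensor sites)
#'
#' Generates time-stamped tri-axial acceleration for one
#' (participant, week, game) segment at each of the five body sites:
#' per-axis Gaussian sensor noise, optional +g on the vertical axis, and
#' Poisson-timed movement bursts shaped as 0.3 s half-sine pulses along the
#' vertical axis. Burst times are shared across sites (one body, one movement)
#' while burst amplitude is scaled per site; the true event times are attached
#' as the `"events"` attribute for oracle-based testing.
#'
#' @param config a [cohort_config()].
#' @param participant_id participant identifier (any string).
#' @param session_week integer week 1..weeks.
#' @param game game label.
#' @param seed base seed; defaults to `config$seed`.
#' @return tibble with columns `participant_id`, `week`, `game`,
#'   `sensor_site`, `t` (seconds), `ax`, `ay`, `az` (m/s^2), carrying a tibble
#'   of true burst times/amplitudes in `attr(, "events")`.
#' @export
#' @examples
#' frames <- simulate_imu_session(demo_config(), "P01", 1, "fruit_ninja", seed = 1)
#' dplyr::count(frames, sensor_site)
simulate_imu_session <- function(config, participant_id, session_week, game,
                                 seed = config$seed) {
  n <- round(config$segment_duration_s * config$sampling_hz)
  t <- (seq_len(n) - 1) / config$sampling_hz
  g <- if (isTRUE(config$include_gravity)) 9.80665 else 0

  withr::with_seed(derive_seed(seed, "imu", participant_id, session_week, game), {
    n_events <- stats::rpois(1, config$peak_rate_hz * config$segment_duration_s)
    events <- sort(stats::runif(n_events, 0, config$segment_duration_s - 0.3))
    amp <- config$peak_amplitude *
      if (config$amplitude_jitter_sdlog > 0) {
        stats::rlnorm(n_events, 0, config$amplitude_jitter_sdlog)
      } else {
        rep(1, n_events)
      }
    frames <- purrr::map(sensor_sites(), function(site) {
      ax <- stats::rnorm(n, 0, config$baseline_noise_sd)
      ay <- stats::rnorm(n, 0, config$baseline_noise_sd)
      az <- stats::rnorm(n, g, config$baseline_noise_sd)
      az <- add_bursts(az, t, events, amp * config$site_scale[[site]])
      tibble::tibble(
        participant_id = participant_id, week = as.integer(session_week),
        game = game, sensor_site = site, t = t, ax = ax, ay = ay, az = az
      )
    })
  })
  out <- dplyr::bind_rows(frames)
  attr(out, "events") <- tibble::tibble(time = events, amplitude = amp)
  out
}

#' Simulate all IMU sessions of a cohort
#'
#' Convenience wrapper over [simulate_imu_session()] for every
#' (participant, week, game) cell of the design.
#'
#' @inheritParams simulate_cohort_roster
#' @param roster optional roster from [simulate_cohort_roster()]; simulated if
#'   absent.
#' @return tibble of sensor samples; the per-session true event counts are
#'   attached as `attr(, "event_counts")`.
#' @export
simulate_imu_cohort <- function(config, roster = NULL, seed = config$seed) {
  roster <- roster %||% simulate_cohort_roster(config, seed)
  cells <- tidyr::expand_grid(
    participant_id = roster$participant_id,
    week = seq_len(config$weeks),
    game = config$games
  )
  sims <- purrr::pmap(cells, function(participant_id, week, game) {
    simulate_imu_session(config, participant_id, week, game, seed = seed)
  })
  counts <- dplyr::mutate(cells, n_events = purrr::map_int(sims, ~ nrow(attr(.x, "events"))))
  out <- dplyr::bind_rows(sims)
  attr(out, "event_counts") <- counts
  out
}

#' Simulate paired pre/post survey responses
#'
#' For each item and each survey completer, draws a bivariate normal
#' (pre, post) pair with the configured means, SDs and within-subject
#' correlation, then discretizes to the Likert scale by rounding half away
#' from zero and clipping to `[scale_min, scale_max]`. The continuous latent
#' pair is kept alongside the discretized response: the latent values carry
#' the configured moments exactly (discretization and clipping bias the
#' observed moments) and serve as ground truth in recovery tests.
#'
#' @inheritParams simulate_cohort_roster
#' @param roster optional roster; simulated if absent.
#' @param discretize logical; apply Likert rounding/clipping (default TRUE).
#' @return tibble with columns `participant_id`, `item_id`, `pre_value`,
#'   `post_value`, `pre_latent`, `post_latent`.
#' @export
#' @examples
#' head(simulate_survey_prepost(demo_config(), seed = 1))
simulate_survey_prepost <- function(config, roster = NULL, seed = config$seed,
                                    discretize = TRUE) {
  roster <- roster %||% simulate_cohort_roster(config, seed)
  completers <- roster$participant_id[roster$survey_completer]
  params <- config$survey_item_params
  rows <- purrr::pmap(params, function(item_id, pre_mean, pre_sd, post_mean,
                                       post_sd, paired_correlation,
                                       scale_min, scale_max, ...) {
    withr::with_seed(derive_seed(seed, "survey", item_id), {
      n <- length(completers)
      z1 <- stats::rnorm(n)
      z2 <- paired_correlation * z1 +
        sqrt(1 - paired_correlation^2) * stats::rnorm(n)
      pre <- pre_mean + pre_sd * z1
      post <- post_mean + post_sd * z2
    })
    likert <- function(x) pmin(scale_max, pmax(scale_min, round_half_out(x, 0)))
    tibble::tibble(
      participant_id = completers, item_id = item_id,
      pre_value = if (discretize) likert(pre) else pre,
      post_value = if (discretize) likert(post) else post,
      pre_latent = pre, post_latent = post
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$item_id, .data$participant_id)
}

draw_mhcsf_items <- function(profile_matrix) {
  vapply(seq_len(14), function(i) {
    sample(0:5, 1, prob = profile_matrix[i, ]) # nolint: seeded by caller
  }, integer(1))
}

#' Simulate weekly MHC-SF questionnaires
#'
#' One 14-item response (frequency codes 0-5) per participant per week, drawn
#' from the participant's latent group profile (`well` or `moderate`) in the
#' configuration. The roster's `true_group` column is the generator's ground
#' truth against which classification can be checked.
#'
#' @inheritParams simulate_survey_prepost
#' @return tibble with columns `participant_id`, `week`,
#'   `item_01` ... `item_14`.
#' @export
#' @examples
#' head(simulate_mhcsf_weekly(demo_config(), seed = 1))
simulate_mhcsf_weekly <- function(config, roster = NULL, seed = config$seed) {
  roster <- roster %||% simulate_cohort_roster(config, seed)
  profiles <- lapply(config$mhcsf_profile, function(pr) {
    if (is.matrix(pr)) pr else matrix(pr, nrow = 14, ncol = 6, byrow = TRUE)
  })
  cells <- tidyr::expand_grid(participant_id = roster$participant_id,
                              week = seq_len(config$weeks))
  cells <- dplyr::left_join(cells,
                            dplyr::select(roster, "participant_id", "true_group"),
                            by = "participant_id")
  items <- purrr::pmap(cells, function(participant_id, week, true_group) {
    withr::with_seed(derive_seed(seed, "mhcsf", participant_id, week), {
      draw_mhcsf_items(profiles[[true_group]])
    })
  })
  item_mat <- do.call(rbind, items)
  colnames(item_mat) <- sprintf("item_%02d", 1:14)
  dplyr::bind_cols(dplyr::select(cells, "participant_id", "week"),
                   tibble::as_tibble(item_mat))
}

#' Simulate daily nutrition logs
#'
#' One record per participant per day over the 28-day study window. Each
#' metric follows `base + drift * (week - 1)` with Gaussian day-to-day noise,
#' rounded half away from zero to a non-negative integer count.
#'
#' @inheritParams simulate_survey_prepost
#' @return tibble with columns `participant_id`, `date`, `milk_servings`,
#'   `water_cups`, `healthy_plate`.
#' @export
#' @examples
#' head(simulate_nutrition_log(demo_config(), seed = 1))
simulate_nutrition_log <- function(config, roster = NULL, seed = config$seed) {
  roster <- roster %||% simulate_cohort_roster(config, seed)
  days <- 7L * config$weeks
  grid <- tidyr::expand_grid(participant_id = roster$participant_id,
                             day = seq_len(days) - 1L)
  week <- grid$day %/% 7L + 1L
  metric_values <- lapply(names(config$nutrition_trend), function(m) {
    p <- config$nutrition_trend[[m]]
    withr::with_seed(derive_seed(seed, "nutrition", m), {
      mu <- p[["base"]] + p[["drift"]] * (week - 1)
      raw <- mu + stats::rnorm(nrow(grid), 0, p[["noise_sd"]])
    })
    pmax(0, round_half_out(raw, 0))
  })
  names(metric_values) <- names(config$nutrition_trend)
  tibble::tibble(
    participant_id = grid$participant_id,
    date = config$study_start + grid$day,
    !!!metric_values
  )
}
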