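# Kinematic metric extraction: z-score peak detection, action count, maximum
# and RMS acceleration, MET conversion and energy expenditure.

#' Peak-detection configuration
#'
#' Settings of the z-score peak detector. The z transform itself is
#' `z = (X - mu) / sigma` with population sigma; everything else (threshold,
#' local-maximum requirement, minimum separation, reference window) is a
#' detector choice, exposed here.
#'
#' @param z_threshold minimum z for a candidate peak (default 2.0).
#' @param min_separation_s minimum time between kept peaks in seconds
#'   (default 0.25); the earlier peak wins.
#' @param windowing `"global"` (mu/sigma over the whole segment, default) or
#'   `"rolling"` (centred rolling window).
#' @param rolling_window_s rolling window width in seconds (default 5; used
#'   only when `windowing = "rolling"`).
#' @return object of class `peak_config`.
#' @export
#' @examples
#' peak_config(z_threshold = 2.5)
peak_config <- function(z_threshold = 2.0, min_separation_s = 0.25,
                        windowing = c("global", "rolling"),
                        rolling_window_s = 5) {
  windowing <- match.arg(windowing)
  if (z_threshold <= 0) abort_input("z_threshold must be > 0")
  if (min_separation_s < 0) abort_input("min_separation_s must be >= 0")
  if (windowing == "rolling" && rolling_window_s <= 0) {
    abort_input("rolling_window_s must be > 0")
  }
  structure(list(z_threshold = z_threshold, min_separation_s = min_separation_s,
                 windowing = windowing, rolling_window_s = rolling_window_s),
            class = "peak_config")
}

#' Acceleration magnitude
#'
#' Euclidean norm of the tri-axial components, the scalar reduction on which
#' all downstream metrics operate. Gravity is not subtracted: the metrics are
#' defined on the raw, gravity-inclusive magnitude (see
#' [compute_segment_metrics()] for the optional subtraction).
#'
#' @param ax,ay,az equal-length numeric vectors, m/s^2.
#' @return numeric vector of per-sample magnitudes (>= 0).
#' @export
#' @examples
#' accel_magnitude(3, 4, 0) # 5
accel_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    abort_input("ax, ay, az must have equal lengths")
  }
  if (length(ax) < 1) abort_input("need at least one sample")
  sqrt(ax^2 + ay^2 + az^2)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

rolling_moments <- function(x, w) {
  # centred rolling mean and population sd via cumulative sums; windows are
  # truncated at the segment edges
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / cnt
  v <- pmax(0, (cs2[hi + 1] - cs2[lo]) / cnt - mu^2)
  list(mean = mu, sd = sqrt(v))
}

#' Standardize a series as z-scores
#'
#' `z = (X - mu) / sigma` with population sigma (divide by N). Reference
#' statistics are taken over the whole segment (default) or over a centred
#' rolling window.
#'
#' @param x numeric series (typically an acceleration magnitude).
#' @param config a [peak_config()].
#' @param fs sampling rate in Hz; required for rolling windowing.
#' @return numeric vector of z-scores.
#' @export
#' @examples
#' zscore_series(c(0, 0, 10, 0, 0)) # spike scores 2.0
zscore_series <- function(x, config = peak_config(), fs = NULL) {
  if (length(x) < 1) abort_input("empty series")
  if (config$windowing == "global") {
    s <- pop_sd(x)
    if (s == 0) abort_input("degenerate signal: zero variance")
    (x - mean(x)) / s
  } else {
    if (is.null(fs)) abort_input("fs is required for rolling windowing")
    mom <- rolling_moments(x, max(3L, round(config$rolling_window_s * fs)))
    if (any(mom$sd == 0)) abort_input("degenerate signal: zero variance in a rolling window")
    (x - mom$mean) / mom$sd
  }
}

#' Detect activity peaks in an acceleration series
#'
#' A sample is a peak when its z-score is at least `z_threshold`, it is a
#' local maximum (`z[i-1] <= z[i] >= z[i+1]`), and it lies at least
#' `min_separation_s` after the previously kept peak (scanning left to right,
#' so the earlier peak wins).
#'
#' A constant (zero-variance) series yields no peaks, with a warning.
#'
#' @param x numeric series (acceleration magnitude).
#' @param fs sampling rate in Hz (needed to convert the minimum separation to
#'   samples; any positive value works when `min_separation_s = 0`).
#' @param config a [peak_config()].
#' @return integer vector of 1-based peak indices.
#' @export
#' @examples
#' detect_peaks(c(0, 0, 10, 0, 0), fs = 1, config = peak_config(min_separation_s = 0))
detect_peaks <- function(x, fs, config = peak_config()) {
  if (length(x) < 3) abort_input("need at least 3 samples to detect peaks")
  if (fs <= 0) abort_input("fs must be > 0")
  z <- tryCatch(zscore_series(x, config, fs), error = function(e) {
    warning("degenerate signal (zero variance): no peaks detected", call. = FALSE)
    NULL
  })
  if (is.null(z)) return(integer(0))
  n <- length(z)
  i <- 2:(n - 1)
  cand <- i[z[i] >= config$z_threshold & z[i - 1] <= z[i] & z[i] >= z[i + 1]]
  if (length(cand) == 0 || config$min_separation_s == 0) {
    return(as.integer(cand))
  }
  min_gap <- config$min_separation_s * fs - sqrt(.Machine$double.eps)
  kept <- integer(length(cand))
  m <- 0L
  last <- -Inf
  for (idx in cand) {
    if (idx - last >= min_gap) {
      m <- m + 1L
      kept[m] <- idx
      last <- idx
    }
  }
  kept[seq_len(m)]
}

#' Action count
#'
#' Normalized peak count: number of detected peaks divided by the number of
#' samples in the segment; dimensionless, in `[0, 1]`.
#'
#' @param peak_indices integer vector of peak indices (as from
#'   [detect_peaks()]).
#' @param n number of samples in the segment (>= 1).
#' @return scalar ratio.
#' @export
#' @examples
#' action_count(c(3), 5) # 0.2
action_count <- function(peak_indices, n) {
  if (length(n) != 1 || n < 1) abort_input("n must be a single count >= 1")
  length(peak_indices) / n
}

#' Maximum acceleration
#'
#' @param x acceleration magnitude series (m/s^2), n >= 1.
#' @return max of the series.
#' @export
max_acceleration <- function(x) {
  if (length(x) < 1) abort_input("empty series")
  max(x)
}

#' Root-mean-square acceleration
#'
#' `sqrt(mean(x^2))`; the movement-intensity summary feeding the MET model.
#'
#' @param x acceleration magnitude series (m/s^2), n >= 1.
#' @return RMS of the series.
#' @export
#' @examples
#' rms_acceleration(c(3, 4)) # sqrt(12.5)
rms_acceleration <- function(x) {
  if (length(x) < 1) abort_input("empty series")
  sqrt(mean(x^2))
}

#' Metabolic equivalents from RMS acceleration
#'
#' Linear model `METs = slope * rms + intercept` (defaults 1.8 and -15). The
#' line goes negative below rms = 8.33 m/s^2, so the value is clamped at zero
#' by default to keep downstream energy non-negative; pass `clamp = FALSE`
#' for the raw regression value (kept for auditing).
#'
#' @param rms RMS acceleration, m/s^2 (>= 0).
#' @param slope,intercept regression coefficients.
#' @param clamp logical; truncate negative METs at 0 (default TRUE).
#' @return MET value(s).
#' @export
#' @examples
#' mets_from_rms(10)                # 3
#' mets_from_rms(5, clamp = FALSE)  # -6
mets_from_rms <- function(rms, slope = 1.8, intercept = -15, clamp = TRUE) {
  if (any(rms < 0)) abort_input("rms must be >= 0")
  raw <- slope * rms + intercept
  if (clamp) pmax(0, raw) else raw
}

#' Energy expenditure
#'
#' `kcal = 1.05 * METs * duration_h * weight_kg`.
#'
#' @param mets MET value(s), >= 0.
#' @param duration_h activity duration in hours, >= 0.
#' @param weight_kg participant body mass in kg, >= 0.
#' @param coefficient leading constant (default 1.05 kcal per MET kg h).
#' @return energy in kcal.
#' @export
#' @examples
#' energy_expenditure(3, 0.5, 60) # 94.5
energy_expenditure <- function(mets, duration_h, weight_kg, coefficient = 1.05) {
  if (any(mets < 0) || any(duration_h < 0) || any(weight_kg < 0)) {
    abort_input("mets, duration_h and weight_kg must all be >= 0")
  }
  coefficient * mets * duration_h * weight_kg
}

segment_metrics_one <- function(t, mag, config, weight_kg) {
  n <- length(mag)
  dt <- stats::median(diff(t))
  fs <- 1 / dt
  duration_h <- (t[n] - t[1] + dt) / 3600
  peaks <- withCallingHandlers(
    detect_peaks(mag, fs = fs, config = config),
    warning = function(w) invokeRestart("muffleWarning")
  )
  rms <- rms_acceleration(mag)
  mets <- mets_from_rms(rms)
  tibble::tibble(
    n_samples = n, duration_h = duration_h, n_peaks = length(peaks),
    action_count = action_count(peaks, n),
    max_acc = max_acceleration(mag),
    rms_acc = rms,
    mets_raw = mets_from_rms(rms, clamp = FALSE),
    mets = mets,
    energy_kcal = energy_expenditure(mets, duration_h, weight_kg)
  )
}

#' Per-sensor and aggregate metrics for sensor segments
#'
#' Computes the kinematic metrics for every
#' (participant, week, game, sensor_site) segment of a tidy sensor table and
#' appends one `AGGREGATE` row per session: mean action count and mean RMS
#' across sensors, maximum of the per-sensor maxima, METs and energy derived
#' from the aggregate RMS.
#'
#' @param sensors tibble with columns `participant_id`, `week`, `game`,
#'   `sensor_site`, `t`, `ax`, `ay`, `az` (the sensor CSV dialect).
#' @param config a [peak_config()].
#' @param weights either a single body mass in kg applied to everyone
#'   (default 70) or a tibble with `participant_id`, `weight_kg`.
#' @param subtract_gravity logical; if TRUE remove standard gravity
#'   (9.80665 m/s^2) from the magnitude before computing metrics (floored at
#'   0). Default FALSE: metrics operate on raw magnitude.
#' @param agg_fun summary used for action count and RMS across sensors
#'   (default [mean()]).
#' @return tibble with one row per segment per sensor site plus one
#'   `AGGREGATE` row per session; columns `participant_id`, `week`, `game`,
#'   `sensor_site`, `n_samples`, `duration_h`, `n_peaks`, `action_count`,
#'   `max_acc`, `rms_acc`, `mets_raw`, `mets`, `energy_kcal`.
#' @export
#' @examples
#' frames <- simulate_imu_session(demo_config(), "P01", 1, "fruit_ninja", seed = 1)
#' compute_segment_metrics(frames)
compute_segment_metrics <- function(sensors, config = peak_config(),
                                    weights = 70, subtract_gravity = FALSE,
                                    agg_fun = mean) {
  assert_cols(sensors, c("participant_id", "week", "game", "sensor_site",
                         "t", "ax", "ay", "az"), "sensor table")
  wtab <- if (is.data.frame(weights)) {
    assert_cols(weights, c("participant_id", "weight_kg"), "weights")
    weights
  } else {
    tibble::tibble(participant_id = unique(sensors$participant_id),
                   weight_kg = as.numeric(weights))
  }
  per_sensor <- sensors |>
    dplyr::left_join(wtab, by = "participant_id") |>
    dplyr::group_by(.data$participant_id, .data$week, .data$game, .data$sensor_site) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      mag <- accel_magnitude(d$ax, d$ay, d$az)
      if (subtract_gravity) mag <- pmax(0, mag - 9.80665)
      segment_metrics_one(d$t, mag, config, d$weight_kg[1])
    }) |>
    dplyr::ungroup()

  agg <- per_sensor |>
    dplyr::left_join(wtab, by = "participant_id") |>
    dplyr::group_by(.data$participant_id, .data$week, .data$game) |>
    dplyr::summarise(
      n_samples = sum(.data$n_samples),
      duration_h = mean(.data$duration_h),
      n_peaks = sum(.data$n_peaks),
      action_count = agg_fun(.data$action_count),
      max_acc = max(.data$max_acc),
      rms_acc = agg_fun(.data$rms_acc),
      weight_kg = .data$weight_kg[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sensor_site = "AGGREGATE",
      mets_raw = mets_from_rms(.data$rms_acc, clamp = FALSE),
      mets = mets_from_rms(.data$rms_acc),
      energy_kcal = energy_expenditure(.data$mets, .data$duration_h, .data$weight_kg)
    ) |>
    dplyr::select(-"weight_kg")

  dplyr::bind_rows(per_sensor, agg) |>
    dplyr::arrange(.data$participant_id, .data$week, .data$game, .data$sensor_site)
}
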