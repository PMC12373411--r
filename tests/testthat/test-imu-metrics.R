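test_that("acceleration magnitude is the per-sample Euclidean norm", {
  expect_equal(accel_magnitude(3, 4, 0), 5)
  expect_equal(accel_magnitude(0, 0, 0), 0)
  expect_equal(accel_magnitude(1, 1, 1), sqrt(3))
  expect_equal(accel_magnitude(c(3, 0), c(4, 0), c(0, 2)), c(5, 2))
  expect_error(accel_magnitude(1:3, 1:2, 1:3), "equal lengths")
})

test_that("z-scores use population sigma over the chosen reference window", {
  z <- zscore_series(c(0, 0, 10, 0, 0))
  expect_equal(z[3], 2)            # mu = 2, population sigma = 4
  expect_equal(mean(z), 0)
  # a sample equal to the mean scores zero
  x <- c(1, 2, 3, 2)
  expect_equal(zscore_series(x)[x == mean(x)], c(0, 0))
  expect_error(zscore_series(rep(7, 10)), "degenerate")
})

test_that("rolling-window z-scores standardize locally", {
  # slow drift plus one spike: global z dilutes the spike, rolling keeps it
  x <- c(seq(0, 50, length.out = 500), seq(50, 0, length.out = 500))
  x[250] <- x[250] + 30
  cfg <- peak_config(windowing = "rolling", rolling_window_s = 2)
  z <- zscore_series(x, cfg, fs = 50)
  expect_gt(z[250], zscore_series(x)[250])
  expect_error(zscore_series(x, cfg), "fs is required")
})

test_that("peak detection applies threshold, local-maximum and separation rules", {
  cfg0 <- peak_config(min_separation_s = 0)
  expect_equal(detect_peaks(c(0, 0, 10, 0, 0), fs = 1, config = cfg0), 3L)
  expect_warning(p <- detect_peaks(rep(3, 10), fs = 50), "degenerate")
  expect_length(p, 0)
  # two identical spikes 0.1 s apart at 50 Hz: separation 0.25 s keeps the first
  x <- rep(0, 100); x[c(40, 45)] <- 10
  kept <- detect_peaks(x, fs = 50, config = peak_config(min_separation_s = 0.25))
  expect_equal(kept, 40L)
  both <- detect_peaks(x, fs = 50, config = peak_config(min_separation_s = 0.05))
  expect_equal(both, c(40L, 45L))
})

test_that("peak detection matches the exhaustive brute-force scan", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      n <- sample(30:800, 1)
      x <- random_accel_series(n)
      fs <- sample(c(10, 25, 50), 1)
      sep <- sample(c(0, 0.1, 0.25, 0.5), 1)
      got <- detect_peaks(x, fs = fs, config = peak_config(min_separation_s = sep))
      expect_identical(got, as.integer(oracle_peaks(x, fs, 2, sep)))
    }
  })
})

test_that("action count is peaks per sample and stays in [0, 1]", {
  expect_equal(action_count(3L, 5), 0.2)
  expect_equal(action_count(integer(0), 1000), 0)
  expect_equal(action_count(seq_len(300), 30000), 0.01)
  expect_error(action_count(1L, 0), "count >= 1")
})

test_that("max and RMS acceleration follow their closed forms", {
  expect_equal(max_acceleration(c(1.2, 3.4, 2.2)), 3.4)
  expect_equal(max_acceleration(rep(2.5, 4)), 2.5)
  expect_equal(max_acceleration(7), 7)
  expect_equal(rms_acceleration(c(3, 4)), sqrt(12.5))
  expect_equal(rms_acceleration(rep(2.5, 9)), 2.5)
  expect_equal(rms_acceleration(c(0, 0, 0)), 0)
  expect_error(rms_acceleration(numeric(0)), "empty")
})

test_that("max acceleration dominates RMS on arbitrary series", {
  withr::with_seed(21, {
    for (i in 1:200) {
      x <- abs(rnorm(sample(2:500, 1), sample(0:20, 1), runif(1, 0.1, 5)))
      expect_gte(max_acceleration(x), rms_acceleration(x))
    }
  })
})

test_that("z-scores, peaks and action count are invariant to positive scaling", {
  withr::with_seed(31, {
    x <- random_accel_series(400)
    for (k in c(0.001, 0.5, 7, 1e4)) {
      expect_equal(zscore_series(k * x), zscore_series(x))
      expect_identical(detect_peaks(k * x, fs = 50), detect_peaks(x, fs = 50))
    }
  })
})

test_that("MET conversion is the printed linear model, clamped at zero", {
  expect_equal(mets_from_rms(10), 3)
  expect_equal(mets_from_rms(12), 6.6)
  expect_equal(mets_from_rms(5, clamp = FALSE), -6)
  expect_equal(mets_from_rms(5), 0)
  expect_error(mets_from_rms(-1), ">= 0")
  # non-decreasing in rms
  r <- seq(0, 20, by = 0.5)
  expect_true(all(diff(mets_from_rms(r)) >= 0))
})

test_that("energy expenditure is 1.05 * METs * hours * kg and linear", {
  expect_equal(energy_expenditure(3, 0.5, 60), 94.5)
  expect_equal(energy_expenditure(0, 2, 80), 0)
  expect_equal(energy_expenditure(1, 1, 1), 1.05)
  expect_equal(energy_expenditure(2 * 3, 0.5, 60), 2 * energy_expenditure(3, 0.5, 60))
  expect_error(energy_expenditure(-1, 1, 1), ">= 0")
})

make_frames <- function(values_by_site, fs = 10) {
  dplyr::bind_rows(lapply(names(values_by_site), function(site) {
    v <- values_by_site[[site]]
    tibble::tibble(participant_id = "P01", week = 1L, game = "g",
                   sensor_site = site, t = (seq_along(v) - 1) / fs,
                   ax = v, ay = 0, az = 0)
  }))
}

test_that("session aggregation: identity, max rule and symmetry across sensors", {
  v <- c(1, 1, 9, 1, 1, 1, 8, 1, 1, 1)
  one <- compute_segment_metrics(make_frames(list(forearm_L = v)),
                                 config = peak_config(min_separation_s = 0))
  agg <- one[one$sensor_site == "AGGREGATE", ]
  per <- one[one$sensor_site == "forearm_L", ]
  for (col in c("action_count", "max_acc", "rms_acc", "mets", "energy_kcal")) {
    expect_equal(agg[[col]], per[[col]], info = col)
  }

  two <- compute_segment_metrics(
    make_frames(list(forearm_L = c(1, 3, 1, 2, 1), forearm_R = c(1, 5, 1, 2, 1))),
    config = peak_config(min_separation_s = 0))
  expect_equal(two$max_acc[two$sensor_site == "AGGREGATE"], 5)

  five <- compute_segment_metrics(
    make_frames(stats::setNames(rep(list(v), 5),
                                c("forearm_L", "forearm_R", "waist_L4", "foot_L", "foot_R"))),
    config = peak_config(min_separation_s = 0))
  agg5 <- five[five$sensor_site == "AGGREGATE", ]
  per5 <- five[five$sensor_site == "forearm_L", ]
  for (col in c("action_count", "max_acc", "rms_acc", "mets", "energy_kcal")) {
    expect_equal(agg5[[col]], per5[[col]], info = col)
  }
})

test_that("per-participant weights feed the energy computation", {
  v <- c(rep(10, 9), 20) # rms > 8.33 so METs > 0
  frames <- make_frames(list(forearm_L = v))
  w <- tibble::tibble(participant_id = "P01", weight_kg = 80)
  m80 <- compute_segment_metrics(frames, weights = w)
  m40 <- compute_segment_metrics(frames, weights = 40)
  agg <- function(m) m$energy_kcal[m$sensor_site == "AGGREGATE"]
  expect_equal(agg(m80), 2 * agg(m40))
  expect_gt(agg(m80), 0)
})
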