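test_that("pupil interpolation is linear across gaps and identity without", {
  tr <- make_pupil(c(4, NA, NA, 8))
  expect_equal(interpolate_pupil(tr)$p, c(4, 4 + 4 / 3, 4 + 8 / 3, 8))
  tr2 <- make_pupil(c(3, 4, 5, 4))
  expect_identical(interpolate_pupil(tr2)$p, tr2$p)
  # leading/trailing gaps take the nearest valid value
  tr3 <- make_pupil(c(NA, 5, 6, NA))
  expect_equal(interpolate_pupil(tr3)$p, c(5, 5, 6, 6))
  expect_error(interpolate_pupil(make_pupil(rep(NA_real_, 5))), "no valid")
})

test_that("interpolated traces match the planted noiseless pupil profile", {
  plan <- event_plan(800, gaze_noise_sd = 0, pupil_noise_sd = 0,
                     pupil_peak = list(time_ms = 600, amplitude = 50,
                                       width_ms = 150)) |>
    add_fixation(0, 300, 400, 300) |>
    add_blink(350, 80) |>
    add_fixation(470, 330, 400, 300)
  res <- generate_trial(plan, seed = 1)
  pupil <- pupil_trace(res$trial)
  blinks <- detect_blinks(pupil)
  interp <- interpolate_pupil(pupil, blinks)
  t <- interp$t_ms
  ideal <- 1000 + 50 * exp(-0.5 * ((t - 600) / 150)^2)
  # away from the blink the trace is exact; across it, linear interpolation
  # over a slowly varying profile stays within a few units
  expect_lt(max(abs(interp$p - ideal)), 6)
  pars <- pupil_parameters(interp, onset_ms = 0)
  expect_lte(abs(pars$pupil_time_to_peak - 600), 10)
})

test_that("pupillometry parameters match hand computation", {
  tr <- make_pupil(c(2, 4, 6, 4, 2))
  pars <- pupil_parameters(tr, onset_ms = 0)
  expect_equal(pars$pupil_mean, 3.6)
  expect_equal(pars$pupil_peak, 6)
  expect_equal(pars$pupil_time_to_peak, 2)
  expect_equal(pars$pupil_auc, 16) # trapezoid by hand
  const <- make_pupil(rep(7, 11))
  pc <- pupil_parameters(const)
  expect_equal(pc$pupil_mean, 7)
  expect_equal(pc$pupil_auc, 7 * 10)
  expect_equal(pc$pupil_time_to_peak, 0)
  expect_error(pupil_parameters(tr, onset_ms = 99), "after the end")
})

test_that("event-family aggregates handle counts, peaks and empties", {
  events <- tibble::tibble(
    kind = c("blink", "blink", "blink"),
    onset_index = 1:3, offset_index = 2:4,
    onset_ms = c(0, 100, 200), offset_ms = c(100, 300, 500),
    duration_ms = c(100, 200, 300),
    x = NA_real_, y = NA_real_, peak_velocity = NA_real_, amplitude = NA_real_
  )
  agg <- aggregate_event_parameters(events)
  expect_equal(agg$blink_count, 3)
  expect_equal(agg$blink_peak_duration, 300)
  expect_equal(agg$blink_mean_duration, 200)
  expect_equal(agg$saccade_count, 0)
  expect_equal(agg$saccade_mean_velocity, 0)
})

test_that("AOI conditioning restricts the fixation family only", {
  fx <- tibble::tibble(
    kind = "fixation", onset_index = 1:10, offset_index = 1:10,
    onset_ms = 1:10, offset_ms = 1:10 + 100, duration_ms = 100,
    x = c(rep(5, 4), rep(50, 6)), y = 5,
    peak_velocity = NA_real_, amplitude = 1
  )
  aoi <- aoi_rectangle(0, 0, 10, 10)
  agg <- aggregate_event_parameters(fx, aoi)
  expect_equal(agg$fixation_count, 4)
  expect_lte(agg$fixation_count, aggregate_event_parameters(fx)$fixation_count)
})

test_that("reading parameters equal run-length analysis of AOI membership", {
  aoi <- aoi_rectangle(0, 0, 10, 10)
  fix_at <- function(inside, durations) {
    tibble::tibble(
      kind = "fixation", onset_index = seq_along(inside),
      offset_index = seq_along(inside),
      onset_ms = seq_along(inside) * 1000,
      offset_ms = seq_along(inside) * 1000 + durations,
      duration_ms = durations,
      x = ifelse(inside, 5, 50), y = 5,
      peak_velocity = NA_real_, amplitude = 1
    )
  }
  rp <- reading_parameters(fix_at(c(TRUE, TRUE, FALSE, TRUE),
                                  c(100, 100, 50, 200)), aoi)
  expect_equal(rp, list(reading_count = 2, first_pass_duration = 200,
                        second_pass_duration = 200))
  rp0 <- reading_parameters(fix_at(rep(FALSE, 4), rep(100, 4)), aoi)
  expect_equal(unlist(rp0), c(reading_count = 0, first_pass_duration = 0,
                              second_pass_duration = 0))
  withr::with_seed(63, {
    for (rep in 1:50) {
      inside <- stats::runif(sample(3:12, 1)) < 0.5
      durations <- stats::runif(length(inside), 50, 400)
      rp <- reading_parameters(fix_at(inside, durations), aoi)
      runs <- runs_oracle(inside)
      expect_equal(rp$reading_count, length(runs))
      expect_equal(rp$first_pass_duration,
                   if (length(runs) >= 1) sum(durations[runs[[1]]]) else 0)
      expect_equal(rp$second_pass_duration,
                   if (length(runs) >= 2) sum(durations[runs[[2]]]) else 0)
    }
  })
  expect_error(reading_parameters(fix_at(TRUE, 100), NULL), "require an AOI")
})

test_that("full extraction yields exactly the 21 named parameters", {
  res <- generate_trial(basic_plan(gaze_noise_sd = 0.005, pupil_noise_sd = 2),
                        seed = 2)
  ps <- suppressWarnings(extract_parameter_set(res$trial))
  expect_identical(setdiff(names(ps), c("subject_id", "stimulus_name")),
                   eye_parameter_names())
  expect_length(eye_parameter_names(), 21)
})

test_that("an event-free constant trial gives zero counts and constant pupil stats", {
  samples <- tibble::tibble(
    timestamp = 0:499,
    gaze_left_x = 400, gaze_left_y = 300,
    gaze_right_x = 400, gaze_right_y = 300,
    pupil_left = 900, pupil_right = 900
  )
  trial <- trial_table(samples, "s1", "flat", 1000)
  ps <- suppressWarnings(extract_parameter_set(trial))
  expect_equal(ps$blink_count, 0)
  expect_equal(ps$saccade_count, 0)
  expect_equal(ps$ms_count, 0)
  expect_equal(ps$fixation_count, 1) # one long dwell
  expect_equal(ps$pupil_mean, 900)
  expect_equal(ps$pupil_peak, 900)
})

test_that("planted event counts are reproduced exactly at zero noise", {
  res <- generate_trial(basic_plan(gaze_noise_sd = 0, pupil_noise_sd = 0),
                        seed = 11)
  ps <- suppressWarnings(extract_parameter_set(res$trial))
  planted <- table(res$truth$kind)
  expect_equal(ps$fixation_count, unname(planted["fixation"]))
  expect_equal(ps$saccade_count, unname(planted["saccade"]))
  expect_equal(ps$blink_count, unname(planted["blink"]))
})

test_that("control normalization subtracts each subject's control mean", {
  base <- suppressWarnings(extract_parameter_set(
    generate_trial(basic_plan(), seed = 1)$trial
  ))
  mk <- function(subj, stim, pupil) {
    out <- base
    out$subject_id <- subj
    out$stimulus_name <- stim
    out$pupil_mean <- pupil
    out
  }
  sets <- dplyr::bind_rows(
    mk("s1", "ctrl1", 8), mk("s1", "ctrl2", 12), mk("s1", "exp1", 15),
    mk("s2", "ctrl1", 10), mk("s2", "ctrl2", 10), mk("s2", "exp1", 14)
  )
  norm <- normalize_with_controls(sets, c("ctrl1", "ctrl2"))
  expect_equal(nrow(norm), 2)
  expect_equal(norm$pupil_mean, c(15 - 10, 14 - 10))
  ratio <- normalize_with_controls(sets, c("ctrl1", "ctrl2"), method = "ratio")
  expect_equal(ratio$pupil_mean, c(1.5, 1.4))

  expect_error(
    normalize_with_controls(dplyr::bind_rows(mk("s1", "ctrl1", 8),
                                             mk("s3", "exp1", 2)), "ctrl1"),
    "s3"
  )
  expect_warning(
    empty <- normalize_with_controls(dplyr::bind_rows(mk("s1", "ctrl1", 8)),
                                     "ctrl1"),
    "all trials are controls"
  )
  expect_equal(nrow(empty), 0)
})
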