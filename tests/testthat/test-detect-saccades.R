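test_that("constant gaze produces no saccades; a jump forces one", {
  expect_equal(nrow(detect_saccades_ivt(make_trace(rep(5, 100), rep(5, 100)))), 0)
  x <- c(rep(0, 5), rep(100, 5))
  sacc <- detect_saccades_ivt(make_trace(x))
  expect_equal(nrow(sacc), 1)
  expect_equal(sacc$peak_velocity, 100 * 1000) # 100 px in one 1 ms step
  expect_equal(sacc$amplitude, 100)
  expect_equal(sacc$offset_index - sacc$onset_index, 1)
})

test_that("planted saccades are recovered with amplitudes within 10%", {
  plan <- event_plan(1200, start_x = 100, start_y = 100, gaze_noise_sd = 0,
                     pupil_noise_sd = 0) |>
    add_fixation(0, 200, 100, 100) |>
    add_saccade(200, 40, 400, 100) |>
    add_fixation(240, 200, 400, 100) |>
    add_saccade(440, 40, 400, 500) |>
    add_fixation(480, 200, 400, 500) |>
    add_saccade(680, 40, 900, 800) |>
    add_fixation(720, 400, 900, 800)
  res <- generate_trial(plan, seed = 1)
  sacc <- detect_saccades_ivt(gaze_trace(res$trial))
  planted <- res$truth[res$truth$kind == "saccade", ]
  expect_equal(nrow(sacc), 3)
  planted_amp <- sqrt((c(400, 400, 900) - c(100, 400, 400))^2 +
                        (c(100, 500, 800) - c(100, 100, 500))^2)
  expect_true(all(abs(sacc$amplitude - planted_amp) / planted_amp < 0.10))
  expect_true(all(abs(sacc$onset_ms - planted$onset_ms_realized) <= 10))
})

test_that("moving-average velocity matches the printed stencil", {
  g <- make_trace(seq(0, 9), rep(0, 10)) # unit steps at 1000 Hz
  v <- compute_ms_velocity(g)
  expect_equal(v$vx[3:8], rep(6 / 6000, 6)) # (2+1-(-1)-(-2)) steps / 6000
  expect_equal(v$vx[c(1, 2, 9, 10)], rep(0, 4))
  expect_equal(v$vy, rep(0, 10))
  withr::with_seed(41, {
    for (rep in 1:5) {
      x <- stats::rnorm(60)
      y <- stats::rnorm(60)
      v <- compute_ms_velocity(make_trace(x, y, sfreq = 500))
      expect_equal(v$vx, stencil_oracle(x, 500))
      expect_equal(v$vy, stencil_oracle(y, 500))
    }
  })
  expect_error(compute_ms_velocity(make_trace(1:4, 1:4)), "at least 5")
})

test_that("the engbert_units switch rescales velocities by S_freq^2 only", {
  g <- make_trace(cumsum(stats::rnorm(50)), cumsum(stats::rnorm(50)))
  v1 <- compute_ms_velocity(g, detection_config())
  v2 <- compute_ms_velocity(g, detection_config(engbert_units = TRUE))
  expect_equal(v2$vx, v1$vx * 1000^2)
})

test_that("the median-based threshold matches its closed form", {
  expect_equal(compute_ms_threshold(c(1, -1, 1, -1, 1, -1), 5), 5)
  withr::with_seed(8, {
    for (rep in 1:10) {
      v <- stats::rnorm(101)
      expect_equal(compute_ms_threshold(v, 5), threshold_oracle(v, 5))
    }
  })
  expect_error(compute_ms_threshold(rep(2, 10)),
               class = "gazemetrics_degenerate_threshold")
})

ms_segment <- function(ramp_len = 12, amplitude = 12, n = 220, onset = 100,
                       noise_sd = 0.005, seed = 14) {
  withr::with_seed(seed, {
    x <- 500 + stats::rnorm(n, sd = noise_sd)
    y <- 600 + stats::rnorm(n, sd = noise_sd)
  })
  if (ramp_len > 0) {
    span <- onset:(onset + ramp_len)
    u <- (span - onset) / ramp_len
    ramp <- (1 - cos(pi * u)) / 2
    x[span] <- x[span] + amplitude * cos(pi / 4) * ramp
    y[span] <- y[span] + amplitude * sin(pi / 4) * ramp
    x[(onset + ramp_len + 1):n] <- x[(onset + ramp_len + 1):n] + amplitude * cos(pi / 4)
    y[(onset + ramp_len + 1):n] <- y[(onset + ramp_len + 1):n] + amplitude * sin(pi / 4)
  }
  make_trace(x, y)
}

test_that("a planted 12-sample microsaccade is detected once, on time", {
  seg <- ms_segment()
  ms <- detect_microsaccades(seg)
  expect_equal(nrow(ms), 1)
  expect_lte(abs(ms$onset_index - 100), 2)
  expect_lte(abs(ms$offset_index - 112), 2)
  expect_equal(ms$amplitude, 12, tolerance = 0.1)
})

test_that("supra-threshold runs below six samples are rejected", {
  cfg <- detection_config()
  smallest_detected <- Inf
  largest_rejected <- 0
  for (ramp_len in 0:10) {
    seg <- ms_segment(ramp_len = ramp_len, amplitude = 6)
    vel <- compute_ms_velocity(seg, cfg)
    thr_x <- compute_ms_threshold(vel$vx, cfg$v_fac)
    thr_y <- compute_ms_threshold(vel$vy, cfg$v_fac)
    k <- (vel$vx / thr_x)^2 + (vel$vy / thr_y)^2
    run_lens <- purrr::map_int(runs_oracle(k > 1), length)
    longest <- if (length(run_lens) == 0) 0L else max(run_lens)
    detected <- nrow(detect_microsaccades(seg, cfg)) > 0
    if (detected) smallest_detected <- min(smallest_detected, longest)
    if (!detected) largest_rejected <- max(largest_rejected, longest)
  }
  expect_equal(smallest_detected, 6)
  expect_lte(largest_rejected, 5)
})

test_that("microsaccade detection is invariant to uniform velocity rescaling", {
  seg <- ms_segment(seed = 77)
  ms1 <- detect_microsaccades(seg)
  scaled <- make_trace(500 + (seg$x - 500) * 3.7, 600 + (seg$y - 600) * 3.7)
  ms2 <- detect_microsaccades(scaled)
  expect_equal(ms1$onset_index, ms2$onset_index)
  expect_equal(ms1$offset_index, ms2$offset_index)
  expect_equal(ms2$amplitude, ms1$amplitude * 3.7, tolerance = 1e-8)
})

test_that("degenerate fixations yield a warning and no microsaccades", {
  seg <- make_trace(rep(400, 40), rep(300, 40))
  expect_warning(ms <- detect_microsaccades(seg), "degenerate")
  expect_equal(nrow(ms), 0)
})

test_that("event amplitude equals the dispersion of the event's gaze points", {
  res <- generate_trial(basic_plan(gaze_noise_sd = 0.005, pupil_noise_sd = 0),
                        seed = 5)
  gaze <- gaze_trace(res$trial)
  sacc <- detect_saccades_ivt(gaze)
  for (i in seq_len(nrow(sacc))) {
    idx <- sacc$onset_index[i]:sacc$offset_index[i]
    expect_equal(sacc$amplitude[i], compute_dispersion(gaze$x[idx], gaze$y[idx]))
  }
})

test_that("events of each kind are time-sorted and non-overlapping", {
  res <- generate_trial(basic_plan(gaze_noise_sd = 0.005, pupil_noise_sd = 2),
                        seed = 29)
  events <- suppressWarnings(detect_events(res$trial))
  for (k in unique(events$kind)) {
    ev <- events[events$kind == k, ]
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$onset_index) > 0), info = k)
      expect_true(all(ev$onset_index[-1] > ev$offset_index[-nrow(ev)]), info = k)
    }
  }
})
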