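test_that("heat-map bins follow the /4 rule and conserve mass", {
  withr::with_seed(3, {
    g <- make_trace(stats::runif(2000, 0, 800), stats::runif(2000, 0, 400))
  })
  grid <- compute_heatmap_grid(g, image_dims = c(400, 800))
  expect_equal(dim(grid$counts), c(100, 200))
  expect_equal(sum(grid$counts), 2000)
  expect_equal(sum(grid$smoothed), 2000, tolerance = 1e-6)
})

test_that("a point source occupies one bin before smoothing", {
  g <- make_trace(rep(400.5, 500), rep(200.5, 500))
  grid <- compute_heatmap_grid(g, image_dims = c(400, 800))
  expect_equal(sum(grid$counts > 0), 1)
  expect_equal(max(grid$counts), 500)
  expect_equal(sum(grid$smoothed), 500, tolerance = 1e-6)
})

test_that("off-screen samples are dropped and counted", {
  g <- make_trace(c(rep(100, 90), rep(-50, 10)), rep(100, 100))
  grid <- compute_heatmap_grid(g, image_dims = c(400, 800))
  expect_equal(grid$n_dropped, 10)
  expect_equal(sum(grid$counts), 90)
})

test_that("uniform gaze is not rejected as non-uniform by chi-square", {
  withr::with_seed(8, {
    g <- make_trace(stats::runif(40000, 0, 80), stats::runif(40000, 0, 40))
  })
  grid <- compute_heatmap_grid(g, image_dims = c(40, 80))
  p <- stats::chisq.test(as.numeric(grid$counts))$p.value
  expect_gt(p, 0.01)
})

test_that("the fixation plot carries one numbered marker per fixation", {
  fx <- tibble::tibble(
    kind = "fixation", onset_index = 1:5, offset_index = 1:5,
    onset_ms = seq(0, 800, by = 200), offset_ms = seq(150, 950, by = 200),
    duration_ms = c(150, 100, 220, 90, 300),
    x = c(100, 300, 500, 700, 900), y = c(100, 200, 300, 400, 500),
    peak_velocity = NA_real_, amplitude = 1
  )
  path <- withr::local_tempfile(fileext = ".png")
  p <- render_plot("fixation_plot", list(fixations = fx), out_path = path)
  expect_true(file.exists(path))
  built <- ggplot2::ggplot_build(p)
  marker_layer <- built$data[[1]]
  label_layer <- built$data[[2]]
  expect_equal(nrow(marker_layer), 5)
  expect_equal(as.character(label_layer$label), as.character(1:5))
  expect_equal(marker_layer$x, fx$x)
})

test_that("the main sequence has a positive velocity-amplitude relation", {
  plan <- event_plan(2400, start_x = 100, start_y = 500, gaze_noise_sd = 0,
                     pupil_noise_sd = 0) |>
    add_fixation(0, 200, 100, 500) |>
    add_saccade(200, 40, 150, 500) |>
    add_fixation(240, 200, 150, 500) |>
    add_saccade(440, 40, 250, 500) |>
    add_fixation(480, 200, 250, 500) |>
    add_saccade(680, 40, 450, 500) |>
    add_fixation(720, 200, 450, 500) |>
    add_saccade(920, 40, 750, 500) |>
    add_fixation(960, 200, 750, 500) |>
    add_saccade(1160, 40, 1200, 500) |>
    add_fixation(1200, 1200, 1200, 500)
  res <- generate_trial(plan, seed = 1)
  sacc <- detect_saccades_ivt(gaze_trace(res$trial))
  expect_equal(nrow(sacc), 5)
  rho <- stats::cor(sacc$amplitude, sacc$peak_velocity, method = "spearman")
  expect_gt(rho, 0.9)
  p <- plot_main_sequence(sacc)
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 5)
})

test_that("aggregate heat maps sum counts before smoothing and list subjects", {
  g1 <- make_trace(rep(100, 50), rep(100, 50))
  g2 <- make_trace(rep(300, 80), rep(200, 80))
  g3 <- make_trace(rep(500, 20), rep(300, 20))
  agg <- aggregate_heatmap_grid(list(s1 = g1, s2 = g2, s3 = g3),
                                image_dims = c(400, 800))
  expect_equal(sum(agg$counts), 150)
  # one subject's aggregate equals that subject's individual grid
  solo <- aggregate_heatmap_grid(list(s1 = g1), image_dims = c(400, 800))
  indiv <- compute_heatmap_grid(g1, image_dims = c(400, 800))
  expect_equal(solo$counts, indiv$counts)
  expect_equal(solo$smoothed, indiv$smoothed)

  path <- withr::local_tempfile(fileext = ".png")
  render_plot("aggregate_heatmap",
              list(gaze_by_subject = list(s1 = g1, s2 = g2, s3 = g3)),
              out_path = path, screen = c(400, 800))
  sidecar <- paste0(tools::file_path_sans_ext(path), "_subjects.txt")
  expect_identical(readLines(sidecar), c("s1", "s2", "s3"))
})

test_that("the microsaccade trace plot shades detected runs", {
  seg_x <- 500 + c(rep(0, 100), (1 - cos(pi * (0:12) / 12)) / 2 * 8,
                   rep(8, 87)) + withr::with_seed(4, stats::rnorm(200, 0, 0.005))
  seg <- make_trace(seg_x, rep(600, 200) + withr::with_seed(5, stats::rnorm(200, 0, 0.005)))
  ms <- detect_microsaccades(seg)
  p <- plot_ms_position_velocity(seg, ms)
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 4 * nrow(ms)) # one shade rect per facet
})

test_that("renderers are pure: identical inputs give identical scene data", {
  withr::with_seed(10, {
    g <- make_trace(stats::runif(500, 0, 800), stats::runif(500, 0, 400))
  })
  p1 <- render_plot("heatmap", list(gaze = g), screen = c(400, 800))
  p2 <- render_plot("heatmap", list(gaze = g), screen = c(400, 800))
  expect_identical(ggplot2::ggplot_build(p1)$data, ggplot2::ggplot_build(p2)$data)
})

test_that("dynamic frame export writes one PNG per decimated step", {
  res <- generate_trial(basic_plan(), seed = 30)
  stem <- file.path(withr::local_tempdir(), "frames")
  paths <- render_plot("dynamic_frames", list(trial = res$trial, decimation = 500),
                       out_path = stem)
  expect_length(paths, ceiling(nrow(res$trial) / 500))
  expect_true(all(file.exists(paths)))
})

test_that("missing inputs per plot kind are reported", {
  expect_error(render_plot("fixation_plot", list()), "requires input")
  expect_error(render_plot("main_sequence", list()), "requires input")
  expect_error(compute_heatmap_grid(make_trace(numeric(0))), "no gaze samples")
})
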