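#' @import ggplot2
NULL

#' Smoothed 2D gaze histogram
#'
#' Bins the gaze samples over the image extent with
#' `floor(n_rows / 4) x floor(n_cols / 4)` bins (a quarter of the pixel
#' resolution per axis), then smooths the count grid with a separable
#' Gaussian kernel (`sigma` in bins, truncated at 3 sigma, zero-padded).
#' Off-screen samples are dropped and counted; the pre-smoothing counts
#' sum exactly to the number of kept samples.
#'
#' @param gaze Gaze trace (columns `x`, `y`); missing samples ignored.
#' @param image_dims `c(n_rows, n_cols)` of the stimulus image / screen
#'   in pixels (rows = height).
#' @param sigma Gaussian smoothing width in bins.
#' @return A list with class `heatmap_grid`: `counts` and `smoothed`
#'   matrices (rows index y), `n_dropped`, `image_dims`.
#' @export
compute_heatmap_grid <- function(gaze, image_dims = c(1024, 1280), sigma = 2) {
  x <- gaze$x; y <- gaze$y
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0) rlang::abort("no gaze samples to bin")
  n_rows <- image_dims[1]; n_cols <- image_dims[2]
  nr <- floor(n_rows / 4); nc <- floor(n_cols / 4)
  if (nr < 1 || nc < 1) rlang::abort("image too small for /4 binning")
  on_screen <- x >= 0 & x <= n_cols & y >= 0 & y <= n_rows
  n_dropped <- sum(!on_screen)
  x <- x[on_screen]; y <- y[on_screen]
  if (length(x) == 0) rlang::abort("all gaze samples are off-screen")
  bx <- pmin(nc, pmax(1L, ceiling(x / n_cols * nc)))
  by <- pmin(nr, pmax(1L, ceiling(y / n_rows * nr)))
  counts <- matrix(0, nrow = nr, ncol = nc)
  tab <- table(factor(by, levels = seq_len(nr)), factor(bx, levels = seq_len(nc)))
  counts[] <- as.numeric(tab)
  structure(
    list(counts = counts, smoothed = gaussian_smooth_2d(counts, sigma),
         n_dropped = n_dropped, image_dims = image_dims, sigma = sigma),
    class = "heatmap_grid"
  )
}

# separable Gaussian convolution (kernel normalized to sum 1, truncated
# at 3 sigma); kernel mass that would spill past the grid edge is folded
# back in by reflection, so the total is conserved exactly
gaussian_smooth_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    rr <- min(r, n - 1)
    kk <- if (rr < r) {
      kt <- stats::dnorm(seq(-rr, rr), sd = sigma)
      kt / sum(kt)
    } else {
      k
    }
    full <- stats::convolve(v, rev(kk), type = "open") # length n + 2*rr
    res <- full[(rr + 1):(rr + n)]
    if (rr > 0) {
      res[1:rr] <- res[1:rr] + rev(full[1:rr])
      res[(n - rr + 1):n] <- res[(n - rr + 1):n] +
        rev(full[(n + rr + 1):(n + 2 * rr)])
    }
    res
  }
  m2 <- apply(m, 2, conv1)
  t(apply(m2, 1, conv1))
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat("<heatmap_grid>", nrow(x$counts), "x", ncol(x$counts), "bins,",
      sum(x$counts), "samples (", x$n_dropped, "dropped )\n")
  invisible(x)
}

heatmap_long <- function(grid) {
  nr <- nrow(grid$smoothed); nc <- ncol(grid$smoothed)
  tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    dplyr::mutate(
      x = (.data$col - 0.5) / nc * grid$image_dims[2],
      y = (.data$row - 0.5) / nr * grid$image_dims[1],
      intensity = as.numeric(t(grid$smoothed))[(.data$row - 1) * nc + .data$col]
    )
}

heat_palette <- function() {
  # fixed "jet"-like ramp, documented default
  c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
    "#FFFF00", "#FF7F00", "#FF0000", "#7F0000")
}

gg_screen <- function(screen, stimulus_image = NULL) {
  p <- ggplot()
  if (!is.null(stimulus_image)) {
    p <- p + annotation_raster(stimulus_image, xmin = 0, xmax = screen[2],
                               ymin = -screen[1], ymax = 0)
  }
  p +
    scale_y_reverse(limits = c(screen[1], 0)) +
    scale_x_continuous(limits = c(0, screen[2])) +
    coord_fixed(expand = FALSE) +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
}

#' Fixation plot
#'
#' Circles at fixation centroids, radius proportional to duration,
#' numbered in temporal order.
#'
#' @param fixations Fixation events tibble.
#' @param screen `c(n_rows, n_cols)` screen size in px.
#' @param stimulus_image Optional raster (e.g. from `png::readPNG()`).
#' @return A ggplot object.
#' @export
plot_fixations <- function(fixations, screen = c(1024, 1280),
                           stimulus_image = NULL) {
  fixations <- fixations[order(fixations$onset_ms), , drop = FALSE]
  fixations$order <- seq_len(nrow(fixations))
  gg_screen(screen, stimulus_image) +
    geom_point(data = fixations,
               aes(x = .data$x, y = .data$y, size = .data$duration_ms),
               shape = 21, colour = "darkgreen", fill = "green", alpha = 0.5) +
    geom_text(data = fixations,
              aes(x = .data$x, y = .data$y, label = .data$order), size = 3) +
    scale_size_area(max_size = 12, guide = "none") +
    labs(title = "Fixation sequence")
}

#' Gaze heat map
#'
#' Filled contours of the smoothed gaze histogram
#' ([compute_heatmap_grid()]) over an optional stimulus image.
#'
#' @param grid A `heatmap_grid`.
#' @param stimulus_image Optional raster.
#' @return A ggplot object.
#' @export
plot_gaze_heatmap <- function(grid, stimulus_image = NULL) {
  long <- heatmap_long(grid)
  long <- long[long$intensity > 0, , drop = FALSE]
  gg_screen(grid$image_dims, stimulus_image) +
    geom_contour_filled(data = heatmap_long(grid),
                        aes(x = .data$x, y = .data$y, z = .data$intensity),
                        alpha = 0.6, bins = 9) +
    scale_fill_manual(values = grDevices::colorRampPalette(heat_palette())(9),
                      guide = "none") +
    labs(title = "Gaze heat map")
}

#' Aggregate heat map over subjects
#'
#' Per-subject count grids are summed *before* smoothing; when plots are
#' saved a sidecar text file lists the included subjects.
#'
#' @param gaze_by_subject Named list of gaze traces (names = subjects).
#' @param image_dims,sigma As in [compute_heatmap_grid()].
#' @return A `heatmap_grid` with attribute `"subjects"`.
#' @export
aggregate_heatmap_grid <- function(gaze_by_subject, image_dims = c(1024, 1280),
                                   sigma = 2) {
  if (length(gaze_by_subject) == 0) rlang::abort("no subjects given")
  grids <- purrr::map(gaze_by_subject, compute_heatmap_grid,
                      image_dims = image_dims, sigma = sigma)
  total <- Reduce(`+`, purrr::map(grids, "counts"))
  out <- structure(
    list(counts = total, smoothed = gaussian_smooth_2d(total, sigma),
         n_dropped = sum(purrr::map_dbl(grids, "n_dropped")),
         image_dims = image_dims, sigma = sigma),
    class = "heatmap_grid"
  )
  attr(out, "subjects") <- names(gaze_by_subject)
  out
}

#' Microsaccade position-velocity plot
#'
#' Four stacked traces — x position, y position, x velocity, y velocity
#' against time — with detected microsaccade runs shaded.
#'
#' @param gaze Gaze trace of one fixation.
#' @param events Microsaccade events detected on that trace.
#' @param cfg A [detection_config()] (for the velocity convention).
#' @return A ggplot object (facetted).
#' @export
plot_ms_position_velocity <- function(gaze, events, cfg = detection_config()) {
  vel <- compute_ms_velocity(gaze, cfg)
  long <- dplyr::bind_rows(
    tibble(t_ms = gaze$t_ms, value = gaze$x, series = "x position (px)"),
    tibble(t_ms = gaze$t_ms, value = gaze$y, series = "y position (px)"),
    tibble(t_ms = gaze$t_ms, value = vel$vx, series = "x velocity"),
    tibble(t_ms = gaze$t_ms, value = vel$vy, series = "y velocity")
  )
  long$series <- factor(long$series, levels = unique(long$series))
  p <- ggplot(long, aes(x = .data$t_ms, y = .data$value)) +
    facet_wrap(~series, ncol = 1, scales = "free_y")
  if (nrow(events) > 0) {
    shade <- tibble(xmin = events$onset_ms, xmax = events$offset_ms)
    p <- p + geom_rect(data = shade,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "orange", alpha = 0.3)
  }
  p + geom_line() + theme_minimal() +
    labs(x = "time (ms)", y = NULL, title = "Microsaccade position / velocity")
}

#' Main-sequence plot
#'
#' Peak velocity against amplitude for (micro)saccadic events, on log
#' axes.
#'
#' @param events Events with `peak_velocity` and `amplitude`.
#' @return A ggplot object.
#' @export
plot_main_sequence <- function(events) {
  ggplot(events, aes(x = .data$amplitude, y = .data$peak_velocity)) +
    geom_point(colour = "steelblue") +
    scale_x_log10() + scale_y_log10() +
    theme_minimal() +
    labs(x = "amplitude (px)", y = "peak velocity",
         title = "Main sequence")
}

#' Render and save a plot
#'
#' Unified entry point over the plot kinds. `inputs` is a named list:
#'
#' * `fixation_plot` — `fixations`
#' * `heatmap` — `gaze` (or a precomputed `grid`)
#' * `aggregate_heatmap` — `gaze_by_subject` (named list); a sidecar
#'   `<out>_subjects.txt` lists the included subjects
#' * `ms_position_velocity` — `gaze`, `events`
#' * `main_sequence` — `events`
#' * `dynamic_frames` — `trial` (plus optional `decimation`, default 100
#'   samples/frame): one PNG per decimated timestep with the gaze dot
#'   and the pupil trace so far
#'
#' @param kind Plot kind.
#' @param inputs Named list of inputs (see above).
#' @param stimulus_image Optional raster drawn under gaze-space plots.
#' @param out_path PNG path (for `dynamic_frames`, a stem: frames are
#'   `<stem>_0001.png`, ...).
#' @param screen `c(n_rows, n_cols)` px.
#' @param cfg Detection config (velocity convention for
#'   `ms_position_velocity`).
#' @return The ggplot object (or list of frame paths for
#'   `dynamic_frames`), invisibly. Files are written when `out_path` is
#'   given.
#' @export
render_plot <- function(kind = c("fixation_plot", "heatmap", "aggregate_heatmap",
                                 "ms_position_velocity", "main_sequence",
                                 "dynamic_frames"),
                        inputs, stimulus_image = NULL, out_path = NULL,
                        screen = c(1024, 1280), cfg = detection_config()) {
  kind <- match.arg(kind)
  need <- function(nm) {
    if (is.null(inputs[[nm]])) {
      rlang::abort(paste0(kind, " requires input '", nm, "'"))
    }
    inputs[[nm]]
  }
  save_png <- function(p, path) {
    ggsave(path, p, width = 7, height = 6, dpi = 100)
  }
  if (kind == "fixation_plot") {
    p <- plot_fixations(need("fixations"), screen, stimulus_image)
    if (!is.null(out_path)) save_png(p, out_path)
    return(invisible(p))
  }
  if (kind == "heatmap") {
    grid <- inputs$grid %||% compute_heatmap_grid(need("gaze"), screen)
    p <- plot_gaze_heatmap(grid, stimulus_image)
    if (!is.null(out_path)) save_png(p, out_path)
    return(invisible(p))
  }
  if (kind == "aggregate_heatmap") {
    grid <- aggregate_heatmap_grid(need("gaze_by_subject"), screen)
    p <- plot_gaze_heatmap(grid, stimulus_image)
    if (!is.null(out_path)) {
      save_png(p, out_path)
      sidecar <- paste0(tools::file_path_sans_ext(out_path), "_subjects.txt")
      writeLines(attr(grid, "subjects"), sidecar)
    }
    return(invisible(p))
  }
  if (kind == "ms_position_velocity") {
    p <- plot_ms_position_velocity(need("gaze"), need("events"), cfg)
    if (!is.null(out_path)) save_png(p, out_path)
    return(invisible(p))
  }
  if (kind == "main_sequence") {
    p <- plot_main_sequence(need("events"))
    if (!is.null(out_path)) save_png(p, out_path)
    return(invisible(p))
  }
  # dynamic_frames
  trial <- need("trial")
  decimation <- inputs$decimation %||% 100
  gaze <- gaze_trace(trial)
  pupil <- pupil_trace(trial)
  steps <- seq(1, nrow(gaze), by = decimation)
  paths <- character()
  for (k in seq_along(steps)) {
    i <- steps[k]
    dot <- gaze[i, , drop = FALSE]
    hist_p <- pupil[seq_len(i), , drop = FALSE]
    p_gaze <- gg_screen(screen, stimulus_image) +
      geom_point(data = dot, aes(x = .data$x, y = .data$y),
                 colour = "red", size = 4, na.rm = TRUE) +
      labs(title = sprintf("t = %.0f ms", gaze$t_ms[i]))
    p_pupil <- ggplot(hist_p, aes(x = .data$t_ms, y = .data$p)) +
      geom_line(na.rm = TRUE) +
      xlim(range(pupil$t_ms)) +
      theme_minimal() + labs(x = "time (ms)", y = "pupil size")
    if (!is.null(out_path)) {
      fp <- sprintf("%s_%04d.png", out_path, k)
      grDevices::png(fp, width = 700, height = 700, res = 100)
      print(p_gaze + theme(plot.margin = margin(2, 2, 2, 2)))
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  invisible(paths)
}

#' Autoplot methods
#'
#' `autoplot()` on a `gaze_events` tibble draws the fixation plot of its
#' fixations (plus a main-sequence inset-free scatter when only
#' saccadic events are present); on a `heatmap_grid` it draws the heat
#' map.
#'
#' @param object A `gaze_events` or `heatmap_grid`.
#' @param screen `c(n_rows, n_cols)` px.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gaze_events
#' @export
autoplot.gaze_events <- function(object, screen = c(1024, 1280), ...) {
  fx <- object[object$kind == "fixation", , drop = FALSE]
  if (nrow(fx) > 0) return(plot_fixations(fx, screen))
  plot_main_sequence(object[object$kind %in% c("saccade", "microsaccade"), ])
}

#' @rdname autoplot.gaze_events
#' @method autoplot heatmap_grid
#' @export
autoplot.heatmap_grid <- function(object, ...) plot_gaze_heatmap(object)
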