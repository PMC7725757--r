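#' I-VT saccade detection
#'
#' Velocity-threshold identification. The pointwise velocity is the
#' sample-to-sample gaze difference `V_t = G_t - G_{t-1}` per axis,
#' converted to pixels/second by multiplying with the sampling frequency
#' so the threshold (`ivt_vel_thresh`, default 40 px/s) is meaningful at
#' any sampling rate. Samples whose speed exceeds the threshold are
#' saccadic; consecutive saccadic samples merge into one saccade. The
#' event's peak velocity is the maximum speed over the run and its
#' amplitude is the dispersion ([compute_dispersion()]) of the run's gaze
#' points, including the pre-movement sample, so a single-step jump has
#' amplitude equal to the step size.
#'
#' Missing gaze samples split the trace; velocities are never taken across
#' a gap.
#'
#' @param gaze Gaze trace from [gaze_trace()].
#' @param cfg A [detection_config()].
#' @return A `gaze_events` tibble, kind `"saccade"`, with `peak_velocity`
#'   in px/s and `amplitude` in px.
#' @export
detect_saccades_ivt <- function(gaze, cfg = detection_config()) {
  sfreq <- trace_sampling_freq(gaze)
  valid <- !is.na(gaze$x) & !is.na(gaze$y)
  segs <- valid_runs(valid)
  out <- purrr::map(segs, function(idx) {
    m <- length(idx)
    if (m < 2) return(NULL)
    vx <- c(0, diff(gaze$x[idx])) * sfreq
    vy <- c(0, diff(gaze$y[idx])) * sfreq
    speed <- sqrt(vx^2 + vy^2)
    sacc <- speed > cfg$ivt_vel_thresh
    sacc[1] <- FALSE # zero-padded edge
    runs <- valid_runs(sacc)
    purrr::map(runs, function(r) {
      lo <- max(1L, r[1] - 1L) # include pre-movement sample
      hi <- r[length(r)]
      member <- idx[lo:hi]
      tibble(
        kind = "saccade",
        onset_index = member[1], offset_index = member[length(member)],
        onset_ms = gaze$t_ms[member[1]],
        offset_ms = gaze$t_ms[member[length(member)]],
        duration_ms = gaze$t_ms[member[length(member)]] - gaze$t_ms[member[1]],
        x = NA_real_, y = NA_real_,
        peak_velocity = max(speed[r]),
        amplitude = compute_dispersion(gaze$x[member], gaze$y[member])
      )
    })
  })
  ev <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(ev) == 0) return(as_gaze_events(empty_events()))
  as_gaze_events(dplyr::arrange(ev, .data$onset_index))
}

#' Moving-average gaze velocity for microsaccade detection
#'
#' Five-tap stencil per axis:
#' `V_t = (G_{t+2} + G_{t+1} - G_{t-1} - G_{t-2}) / (6 * S_freq)`.
#' The first and last two samples are set to zero. The divisor is applied
#' exactly in this form by default; with `engbert_units = TRUE` in the
#' configuration the result is multiplied by `S_freq^2`, recovering a
#' per-second-style scale. Microsaccade detection is invariant to this
#' choice because the adaptive threshold rescales identically.
#'
#' @param gaze Gaze trace (columns `t_ms`, `x`, `y`), at least 5 samples,
#'   no missing values.
#' @param cfg A [detection_config()].
#' @return Tibble with columns `vx`, `vy`, same length as the trace.
#' @export
compute_ms_velocity <- function(gaze, cfg = detection_config()) {
  n <- nrow(gaze)
  if (n < 5) rlang::abort("moving-average velocity needs at least 5 samples")
  if (anyNA(gaze$x) || anyNA(gaze$y)) {
    rlang::abort("gaze segment must not contain missing samples")
  }
  sfreq <- trace_sampling_freq(gaze)
  stencil <- function(g) {
    v <- numeric(n)
    t <- 3:(n - 2)
    v[t] <- (g[t + 2] + g[t + 1] - g[t - 1] - g[t - 2]) / (6 * sfreq)
    if (cfg$engbert_units) v <- v * sfreq^2
    v
  }
  tibble(vx = stencil(gaze$x), vy = stencil(gaze$y))
}

#' Median-based microsaccade velocity threshold
#'
#' `V_thresh = V_fac * sqrt(median((V - median(V))^2))`, computed per
#' axis. The square-root of the median squared deviation from the median
#' is a robust spread estimate; multiplying by `v_fac` (default 5) gives
#' the detection threshold.
#'
#' @param v Velocity vector for one axis (non-empty).
#' @param v_fac Threshold multiplier.
#' @return The scalar threshold.
#' @section Degenerate traces: a constant velocity vector has zero spread
#'   and no meaningful threshold; an error of class
#'   `gazemetrics_degenerate_threshold` is raised instructing the caller
#'   to skip microsaccade detection for that fixation.
#' @export
#' @examples
#' compute_ms_threshold(c(1, -1, 1, -1, 1, -1), 5) # 5
compute_ms_threshold <- function(v, v_fac = 5) {
  if (length(v) == 0) rlang::abort("velocity vector is empty")
  sigma <- sqrt(stats::median((v - stats::median(v))^2))
  if (!is.finite(sigma) || sigma == 0) {
    rlang::abort(
      "velocity spread is zero; skip microsaccade detection for this fixation",
      class = "gazemetrics_degenerate_threshold"
    )
  }
  v_fac * sigma
}

#' Microsaccade detection within a fixation
#'
#' Operates on the gaze samples of a single fixation. Moving-average
#' velocities ([compute_ms_velocity()]) are compared against per-axis
#' adaptive thresholds ([compute_ms_threshold()]) through the elliptic
#' criterion `k = (vx / vx_thresh)^2 + (vy / vy_thresh)^2`; maximal runs
#' with `k > 1` lasting at least `ms_min_samples` (default 6) samples are
#' microsaccades. Each event's peak velocity is `max(sqrt(vx^2 + vy^2))`
#' over the run and its amplitude the dispersion of the run's gaze points.
#'
#' @param gaze Gaze trace restricted to one fixation (no missing samples).
#' @param cfg A [detection_config()].
#' @return A `gaze_events` tibble, kind `"microsaccade"`. Degenerate
#'   thresholds (constant-velocity segments) yield zero rows with a
#'   warning; segments shorter than `5 + ms_min_samples` samples yield
#'   zero rows.
#' @export
detect_microsaccades <- function(gaze, cfg = detection_config()) {
  n <- nrow(gaze)
  if (n < 5 + cfg$ms_min_samples) return(as_gaze_events(empty_events()))
  vel <- compute_ms_velocity(gaze, cfg)
  thr <- tryCatch(
    list(
      x = compute_ms_threshold(vel$vx, cfg$v_fac),
      y = compute_ms_threshold(vel$vy, cfg$v_fac)
    ),
    gazemetrics_degenerate_threshold = function(e) NULL
  )
  if (is.null(thr)) {
    rlang::warn("degenerate velocity threshold; no microsaccades reported for this fixation")
    return(as_gaze_events(empty_events()))
  }
  k <- (vel$vx / thr$x)^2 + (vel$vy / thr$y)^2
  runs <- valid_runs(k > 1)
  runs <- purrr::keep(runs, ~ length(.x) >= cfg$ms_min_samples)
  if (length(runs) == 0) return(as_gaze_events(empty_events()))
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  ev <- purrr::map(runs, function(r) {
    tibble(
      kind = "microsaccade",
      onset_index = r[1], offset_index = r[length(r)],
      onset_ms = gaze$t_ms[r[1]], offset_ms = gaze$t_ms[r[length(r)]],
      duration_ms = gaze$t_ms[r[length(r)]] - gaze$t_ms[r[1]],
      x = NA_real_, y = NA_real_,
      peak_velocity = max(speed[r]),
      amplitude = compute_dispersion(gaze$x[r], gaze$y[r])
    )
  })
  as_gaze_events(dplyr::bind_rows(ev))
}

#' Detect all event families in one trial
#'
#' Runs the full detection cascade: blink detection on the pupil trace,
#' blink masking of the gaze trace, I-DT fixations, I-VT saccades, and
#' per-fixation microsaccade detection. Microsaccade indices are reported
#' in trial coordinates.
#'
#' @param trial Base-format trial tibble.
#' @param cfg A [detection_config()].
#' @return A `gaze_events` tibble holding all four kinds, time-sorted
#'   within kind.
#' @export
detect_events <- function(trial, cfg = detection_config()) {
  pupil <- pupil_trace(trial, eye = cfg$eye)
  blinks <- detect_blinks(pupil, cfg)
  gaze <- gaze_trace(trial, eye = cfg$eye, mask_events = blinks)
  fixations <- detect_fixations_idt(gaze, cfg)
  saccades <- detect_saccades_ivt(gaze, cfg)
  micro <- purrr::map(seq_len(nrow(fixations)), function(i) {
    idx <- seq(fixations$onset_index[i], fixations$offset_index[i])
    seg <- gaze[idx, ]
    attr(seg, "sampling_freq") <- attr(gaze, "sampling_freq")
    ms <- detect_microsaccades(seg, cfg)
    ms$onset_index <- ms$onset_index + idx[1] - 1L
    ms$offset_index <- ms$offset_index + idx[1] - 1L
    ms
  })
  as_gaze_events(dplyr::bind_rows(blinks, fixations, saccades, dplyr::bind_rows(micro)))
}
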