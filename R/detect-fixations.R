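#' Dispersion of a gaze window
#'
#' The dispersion combines the x and y ranges of the points:
#' `D = sqrt((max(x) - min(x))^2 + (max(y) - min(y))^2)`. The same formula
#' doubles as the amplitude of saccade and microsaccade sequences, so both
#' call this single implementation.
#'
#' @param x,y Pixel coordinate vectors of equal, positive length.
#' @return Dispersion in pixels (0 for a single point).
#' @export
#' @examples
#' compute_dispersion(c(0, 3, 0), c(0, 0, 4)) # 5
compute_dispersion <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) rlang::abort("dispersion of an empty window")
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) rlang::abort("dispersion window contains missing gaze")
  sqrt((max(x) - min(x))^2 + (max(y) - min(y))^2)
}

#' I-DT fixation detection
#'
#' Dispersion-threshold identification. A candidate window of the minimum
#' fixation length (`w_thresh_ms`) is placed at the start of the trace; if
#' its dispersion is at most `d_thresh_px` the window grows one sample at a
#' time until the dispersion exceeds the threshold, at which point all
#' window points except the last form a fixation and the next candidate
#' window starts after it. If the initial window already exceeds the
#' threshold, its start slides by one sample. A window still within
#' threshold at the end of the trace is emitted as a trailing fixation.
#' Growth continues while `D <= D_thresh` (ties grow).
#'
#' The minimum window is `round(w_thresh_ms * S_freq / 1000) + 1` samples
#' so that the shortest reportable fixation *spans* `w_thresh_ms`
#' (offset - onset >= 50 ms at defaults).
#'
#' Missing gaze samples (e.g. masked blinks) split the trace; each valid
#' segment is processed independently.
#'
#' @param gaze Gaze trace from [gaze_trace()] (columns `t_ms`, `x`, `y`).
#' @param cfg A [detection_config()].
#' @return A `gaze_events` tibble, kind `"fixation"`, with the centroid of
#'   the member points in `x`, `y`.
#' @export
detect_fixations_idt <- function(gaze, cfg = detection_config()) {
  sfreq <- trace_sampling_freq(gaze)
  w0 <- as.integer(round(cfg$w_thresh_ms * sfreq / 1000)) + 1L
  if (w0 < 2) rlang::abort("w_thresh_ms must cover at least 2 samples")
  valid <- !is.na(gaze$x) & !is.na(gaze$y)
  segs <- valid_runs(valid)
  out <- purrr::map(segs, function(idx) {
    if (length(idx) < w0) return(NULL)
    spans <- idt_segment(gaze$x[idx], gaze$y[idx], w0, cfg$d_thresh_px)
    purrr::map(spans, function(sp) {
      member <- idx[sp[1]:sp[2]]
      tibble(
        kind = "fixation",
        onset_index = member[1], offset_index = member[length(member)],
        onset_ms = gaze$t_ms[member[1]],
        offset_ms = gaze$t_ms[member[length(member)]],
        duration_ms = gaze$t_ms[member[length(member)]] - gaze$t_ms[member[1]],
        x = mean(gaze$x[member]), y = mean(gaze$y[member]),
        peak_velocity = NA_real_,
        amplitude = compute_dispersion(gaze$x[member], gaze$y[member])
      )
    })
  })
  ev <- dplyr::bind_rows(purrr::flatten(out))
  if (nrow(ev) == 0) return(as_gaze_events(empty_events()))
  as_gaze_events(dplyr::arrange(ev, .data$onset_index))
}

# the windowing loop on one NA-free segment; returns list of c(start, end)
# (indices local to the segment). Running min/max makes growth O(1).
idt_segment <- function(x, y, w0, d_thresh) {
  n <- length(x)
  fixations <- list()
  i <- 1L
  while (i + w0 - 1L <= n) {
    j <- i + w0 - 1L
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    d <- sqrt((xmax - xmin)^2 + (ymax - ymin)^2)
    if (d > d_thresh) {
      i <- i + 1L
      next
    }
    while (j + 1L <= n) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      nd <- sqrt((nxmax - nxmin)^2 + (nymax - nymin)^2)
      if (nd > d_thresh) break
      j <- j + 1L
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
    }
    fixations[[length(fixations) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  fixations
}
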