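#' Noise-based blink detection with onset/offset refinement
#'
#' Blinks appear as runs of lost pupil samples. The initial onset is the
#' last valid sample before a missing run and the initial offset the first
#' valid sample after it. Because the eyelid already occludes the pupil
#' while the tracker still reports (noisy, shrinking) values, both
#' boundaries are then refined: the pupil series is smoothed with a
#' centred moving average (`blink_smooth_window_ms`), adjacent-sample
#' differences are inspected, and the onset is walked backward while the
#' smoothed values rise going backward (i.e. the pupil was falling into
#' the blink), the offset forward while the values rise going forward (the
#' pupil recovering). Each boundary stops at the end of its monotone run
#' or at the trace edge. Refined windows never shrink relative to the raw
#' missing run; overlapping refined windows are merged.
#'
#' @param pupil Pupil trace from [pupil_trace()] (columns `t_ms`, `p`).
#' @param cfg A [detection_config()].
#' @return A `gaze_events` tibble with one row per blink (kind `"blink"`).
#'   A trace with no missing samples yields zero rows; an all-missing
#'   trace yields one blink spanning the trace, with a warning.
#' @export
#' @examples
#' p <- c(10, 10, 9, 8, NA, NA, NA, 8, 9, 10, 10)
#' tr <- tibble::tibble(t_ms = 0:10, p = p)
#' attr(tr, "sampling_freq") <- 1000
#' detect_blinks(tr, detection_config())
detect_blinks <- function(pupil, cfg = detection_config()) {
  sfreq <- trace_sampling_freq(pupil)
  p <- pupil$p
  n <- length(p)
  w <- max(1L, round(cfg$blink_smooth_window_ms / 1000 * sfreq))
  if (n <= w) rlang::abort("pupil trace must be longer than the smoothing window")
  missing <- is.na(p)
  if (!any(missing)) return(as_gaze_events(empty_events()))
  if (all(missing)) {
    rlang::warn("pupil trace is entirely missing; treating it as one blink")
    ev <- tibble(
      kind = "blink", onset_index = 1L, offset_index = n,
      onset_ms = pupil$t_ms[1], offset_ms = pupil$t_ms[n],
      duration_ms = pupil$t_ms[n] - pupil$t_ms[1],
      x = NA_real_, y = NA_real_,
      peak_velocity = NA_real_, amplitude = NA_real_
    )
    return(as_gaze_events(ev))
  }

  s <- moving_average(p, w)

  runs <- valid_runs(missing)
  bounds <- purrr::map(runs, function(idx) {
    gap_start <- idx[1]
    gap_end <- idx[length(idx)]
    onset <- if (gap_start > 1) gap_start - 1L else gap_start
    offset <- if (gap_end < n) gap_end + 1L else gap_end
    # onset walk: backward while the smoothed series increases going back
    if (gap_start > 1) {
      j <- onset
      while (j > 1 && !is.na(s[j - 1]) && !is.na(s[j]) && s[j - 1] > s[j]) {
        j <- j - 1L
      }
      onset <- j
    }
    # offset walk: forward while the smoothed series increases going forward
    if (gap_end < n) {
      j <- offset
      while (j < n && !is.na(s[j + 1]) && !is.na(s[j]) && s[j + 1] > s[j]) {
        j <- j + 1L
      }
      offset <- j
    }
    c(onset, offset)
  })

  onsets <- purrr::map_int(bounds, 1)
  offsets <- purrr::map_int(bounds, 2)
  ord <- order(onsets)
  onsets <- onsets[ord]; offsets <- offsets[ord]
  # merge overlapping refined windows
  keep_on <- onsets[1]; keep_off <- offsets[1]
  merged_on <- integer(); merged_off <- integer()
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] <= keep_off) {
      keep_off <- max(keep_off, offsets[i])
    } else {
      merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, keep_off)
      keep_on <- onsets[i]; keep_off <- offsets[i]
    }
  }
  merged_on <- c(merged_on, keep_on); merged_off <- c(merged_off, keep_off)

  ev <- tibble(
    kind = "blink",
    onset_index = merged_on, offset_index = merged_off,
    onset_ms = pupil$t_ms[merged_on], offset_ms = pupil$t_ms[merged_off],
    duration_ms = pupil$t_ms[merged_off] - pupil$t_ms[merged_on],
    x = NA_real_, y = NA_real_,
    peak_velocity = NA_real_, amplitude = NA_real_
  )
  as_gaze_events(ev)
}

# Centred moving average of window length w, applied within each
# contiguous valid (non-NA) segment so gaps are never averaged across.
# Interior samples use the full w-sample window (support exactly w);
# where the window would cross a segment boundary it shrinks
# symmetrically, preserving local monotone structure near blink flanks.
moving_average <- function(x, w) {
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  s <- rep(NA_real_, n)
  for (seg in valid_runs(!is.na(x))) {
    a <- seg[1]; b <- seg[length(seg)]
    for (i in seg) {
      if (i - half_lo >= a && i + half_hi <= b) {
        s[i] <- mean(x[(i - half_lo):(i + half_hi)])
      } else {
        r <- min(i - a, b - i, half_hi)
        s[i] <- mean(x[(i - r):(i + r)])
      }
    }
  }
  s
}
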