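#' Detection configuration
#'
#' Bundles the tunable thresholds of the four event detectors.
#'
#' * `w_thresh_ms` — I-DT minimum fixation duration (window threshold), in
#'   ms. Default 50 ms.
#' * `d_thresh_px` — I-DT dispersion threshold in pixels. The dispersion of
#'   a window is `sqrt(range(x)^2 + range(y)^2)`. Default 25 px
#'   (package-chosen; the I-DT literature leaves it to screen geometry).
#' * `ivt_vel_thresh` — I-VT point-velocity threshold in pixels/second;
#'   samples moving faster are saccadic. Default 40 px/s.
#' * `v_fac` — microsaccade threshold multiplier applied to the
#'   median-based velocity spread estimate, per axis. Default 5.
#' * `ms_min_samples` — minimum run length (samples) for a supra-threshold
#'   sequence to count as a microsaccade. Default 6.
#' * `blink_smooth_window_ms` — moving-average window used to smooth the
#'   pupil series before blink onset/offset refinement. Default 10 ms.
#' * `eye` — which eye drives detection: `"average"` (mean of valid eyes,
#'   the default), `"left"` or `"right"`.
#' * `engbert_units` — if `TRUE`, microsaccade velocities are multiplied by
#'   `S_freq^2` relative to the default convention (restoring a
#'   per-second-style scale). Detection is unaffected — the threshold
#'   rescales identically — only reported peak velocities change.
#'
#' @param w_thresh_ms,d_thresh_px,ivt_vel_thresh,v_fac,ms_min_samples,blink_smooth_window_ms
#'   Positive scalars, see above.
#' @param eye One of `"average"`, `"left"`, `"right"`.
#' @param engbert_units Logical.
#' @return A list with class `detection_config`.
#' @export
#' @examples
#' detection_config()
#' detection_config(d_thresh_px = 35, eye = "left")
detection_config <- function(w_thresh_ms = 50,
                             d_thresh_px = 25,
                             ivt_vel_thresh = 40,
                             v_fac = 5,
                             ms_min_samples = 6,
                             blink_smooth_window_ms = 10,
                             eye = c("average", "left", "right"),
                             engbert_units = FALSE) {
  eye <- match.arg(eye)
  vals <- c(
    w_thresh_ms = w_thresh_ms, d_thresh_px = d_thresh_px,
    ivt_vel_thresh = ivt_vel_thresh, v_fac = v_fac,
    ms_min_samples = ms_min_samples,
    blink_smooth_window_ms = blink_smooth_window_ms
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all detection thresholds must be positive and finite")
  }
  structure(
    list(
      w_thresh_ms = w_thresh_ms, d_thresh_px = d_thresh_px,
      ivt_vel_thresh = ivt_vel_thresh, v_fac = v_fac,
      ms_min_samples = as.integer(ms_min_samples),
      blink_smooth_window_ms = blink_smooth_window_ms,
      eye = eye, engbert_units = isTRUE(engbert_units)
    ),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  cat(sprintf("  I-DT: W_thresh %g ms, D_thresh %g px\n", x$w_thresh_ms, x$d_thresh_px))
  cat(sprintf("  I-VT: velocity threshold %g px/s\n", x$ivt_vel_thresh))
  cat(sprintf("  microsaccades: V_fac %g, min run %d samples\n", x$v_fac, x$ms_min_samples))
  cat(sprintf("  blinks: smoothing window %g ms\n", x$blink_smooth_window_ms))
  cat(sprintf("  eye: %s; engbert_units: %s\n", x$eye, x$engbert_units))
  invisible(x)
}
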