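#' Extract a gaze trace from a trial
#'
#' Reduces binocular samples to a single (x, y) pixel series. With
#' `eye = "average"` each coordinate is the mean of the eyes that are valid
#' at that sample; a sample is `NA` only when both eyes are lost. Samples
#' inside `mask_events` (typically refined blink windows) are set to `NA`
#' so they cannot corrupt dispersion or velocity computations downstream.
#'
#' @param trial Base-format trial tibble.
#' @param eye `"average"`, `"left"` or `"right"`.
#' @param mask_events Optional event tibble (e.g. from [detect_blinks()]);
#'   samples between each event's onset and offset index inclusive are
#'   masked.
#' @return Tibble with columns `t_ms`, `x`, `y` and attribute
#'   `sampling_freq`.
#' @export
gaze_trace <- function(trial, eye = c("average", "left", "right"),
                       mask_events = NULL) {
  eye <- match.arg(eye)
  trial <- validate_trial_table(trial)
  lx <- trial$gaze_left_x; ly <- trial$gaze_left_y
  rx <- trial$gaze_right_x; ry <- trial$gaze_right_y
  if (eye == "left") {
    x <- lx; y <- ly
  } else if (eye == "right") {
    x <- rx; y <- ry
  } else {
    x <- rowMeans(cbind(lx, rx), na.rm = TRUE)
    y <- rowMeans(cbind(ly, ry), na.rm = TRUE)
    x[is.nan(x)] <- NA_real_
    y[is.nan(y)] <- NA_real_
  }
  if (!is.null(mask_events) && nrow(mask_events) > 0) {
    for (i in seq_len(nrow(mask_events))) {
      idx <- seq(mask_events$onset_index[i], mask_events$offset_index[i])
      x[idx] <- NA_real_
      y[idx] <- NA_real_
    }
  }
  out <- tibble(t_ms = trial$timestamp, x = x, y = y)
  attr(out, "sampling_freq") <- trial_sampling_freq(trial)
  out
}

#' Extract a pupil trace from a trial
#'
#' Lost samples (vendor 0 or missing) become `NA`. With `eye = "average"`
#' the mean of valid eyes is used.
#'
#' @inheritParams gaze_trace
#' @return Tibble with columns `t_ms`, `p` and attribute `sampling_freq`.
#' @export
pupil_trace <- function(trial, eye = c("average", "left", "right")) {
  eye <- match.arg(eye)
  trial <- validate_trial_table(trial)
  pl <- trial$pupil_left
  pr <- trial$pupil_right
  pl[!is.na(pl) & pl == 0] <- NA_real_
  pr[!is.na(pr) & pr == 0] <- NA_real_
  p <- switch(eye,
    left = pl,
    right = pr,
    average = {
      m <- rowMeans(cbind(pl, pr), na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      m
    }
  )
  out <- tibble(t_ms = trial$timestamp, p = p)
  attr(out, "sampling_freq") <- trial_sampling_freq(trial)
  out
}

trace_sampling_freq <- function(trace) {
  sf <- attr(trace, "sampling_freq")
  if (is.null(sf)) {
    dt <- stats::median(diff(trace$t_ms))
    sf <- 1000 / dt
  }
  sf
}

# contiguous runs where `valid` is TRUE, as a list of index vectors
valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], seq.int)
}

empty_events <- function() {
  tibble(
    kind = character(), onset_index = integer(), offset_index = integer(),
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    x = numeric(), y = numeric(),
    peak_velocity = numeric(), amplitude = numeric()
  )
}

as_gaze_events <- function(events) {
  events <- as_tibble(events)
  class(events) <- c("gaze_events", class(events))
  events
}
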