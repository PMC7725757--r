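# shared plan builders and independent oracles used across test files

make_trace <- function(x, y = rep(0, length(x)), sfreq = 1000) {
  out <- tibble::tibble(t_ms = (seq_along(x) - 1) * 1000 / sfreq, x = x, y = y)
  attr(out, "sampling_freq") <- sfreq
  out
}

make_pupil <- function(p, sfreq = 1000) {
  out <- tibble::tibble(t_ms = (seq_along(p) - 1) * 1000 / sfreq, p = p)
  attr(out, "sampling_freq") <- sfreq
  out
}

# a small three-fixation plan with saccades and one blink; no microsaccade
basic_plan <- function(gaze_noise_sd = 0, pupil_noise_sd = 0) {
  event_plan(duration_ms = 1500, start_x = 200, start_y = 200,
             gaze_noise_sd = gaze_noise_sd, pupil_noise_sd = pupil_noise_sd) |>
    add_fixation(0, 300, 200, 200) |>
    add_saccade(300, 30, 600, 400) |>
    add_fixation(330, 370, 600, 400) |>
    add_saccade(700, 30, 300, 700) |>
    add_fixation(730, 370, 300, 700) |>
    add_blink(1150, 80) |>
    add_fixation(1255, 245, 300, 700)
}

# naive I-DT re-execution: recompute dispersion from scratch at every step
idt_oracle <- function(x, y, w0, d_thresh) {
  disp <- function(i, j) {
    sqrt((max(x[i:j]) - min(x[i:j]))^2 + (max(y[i:j]) - min(y[i:j]))^2)
  }
  n <- length(x)
  spans <- list()
  i <- 1
  while (i + w0 - 1 <= n) {
    j <- i + w0 - 1
    if (disp(i, j) > d_thresh) {
      i <- i + 1
      next
    }
    while (j + 1 <= n && disp(i, j + 1) <= d_thresh) j <- j + 1
    spans[[length(spans) + 1]] <- c(i, j)
    i <- j + 1
  }
  spans
}

# direct 5-tap stencil, plain loop
stencil_oracle <- function(g, sfreq) {
  n <- length(g)
  v <- numeric(n)
  for (t in 3:(n - 2)) {
    v[t] <- (g[t + 2] + g[t + 1] - g[t - 1] - g[t - 2]) / (6 * sfreq)
  }
  v
}

# sort-based median, avoiding stats::median
manual_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

threshold_oracle <- function(v, v_fac) {
  v_fac * sqrt(manual_median((v - manual_median(v))^2))
}

# convex-polygon containment by half-plane intersection (vertices CCW)
halfplane_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cross <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    if (cross < -1e-9) return(FALSE)
  }
  TRUE
}

# manual run-length encoding of a logical vector (no rle())
runs_oracle <- function(flags) {
  runs <- list()
  i <- 1
  while (i <= length(flags)) {
    if (flags[i]) {
      j <- i
      while (j + 1 <= length(flags) && flags[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- i:j
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# hand-traceable blink refinement: centred moving average with symmetric
# shrink at segment edges, then strict monotone walks
blink_oracle <- function(p, w) {
  n <- length(p)
  segs <- split(seq_len(n), cumsum(c(TRUE, diff(is.na(p)) != 0)))
  s <- rep(NA_real_, n)
  half_lo <- (w - 1) %/% 2
  half_hi <- w - 1 - half_lo
  for (seg in segs) {
    if (anyNA(p[seg])) next
    a <- seg[1]; b <- seg[length(seg)]
    for (i in seg) {
      if (i - half_lo >= a && i + half_hi <= b) {
        s[i] <- mean(p[(i - half_lo):(i + half_hi)])
      } else {
        r <- min(i - a, b - i, half_hi)
        s[i] <- mean(p[(i - r):(i + r)])
      }
    }
  }
  gaps <- runs_oracle(is.na(p))
  lapply(gaps, function(g) {
    onset <- if (g[1] > 1) g[1] - 1 else g[1]
    offset <- if (g[length(g)] < n) g[length(g)] + 1 else g[length(g)]
    if (g[1] > 1) {
      while (onset > 1 && !is.na(s[onset - 1]) && s[onset - 1] > s[onset]) {
        onset <- onset - 1
      }
    }
    if (g[length(g)] < n) {
      while (offset < n && !is.na(s[offset + 1]) && s[offset + 1] > s[offset]) {
        offset <- offset + 1
      }
    }
    c(onset, offset)
  })
}
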