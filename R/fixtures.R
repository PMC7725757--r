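#' Build a synthetic trial plan
#'
#' A plan is the declarative description of one synthetic trial: overall
#' duration, starting gaze position, pupil baseline, noise levels, an
#' optional pupil "peak" bump, and a set of planted events added with
#' [add_fixation()], [add_saccade()], [add_microsaccade()] and
#' [add_blink()]. [generate_trial()] realizes a plan into samples plus a
#' ground-truth record of where each event landed.
#'
#' Gaze noise is isotropic Gaussian jitter; pupil noise is additive
#' Gaussian. Saccades and microsaccades are realized with a raised-cosine
#' displacement profile so velocity peaks mid-movement, giving
#' main-sequence structure. Blinks are realized as a missing run flanked
#' by a smooth 20 ms pupil descent before and ascent after the gap — the
#' structure the blink-refinement algorithm exploits; the recorded ground
#' truth spans flank start to flank end.
#'
#' @param duration_ms Trial length in ms.
#' @param start_x,start_y Initial gaze position (px). Defaults centre a
#'   1280 x 1024 screen.
#' @param pupil_baseline Baseline pupil size (vendor units).
#' @param gaze_noise_sd Gaze jitter standard deviation (px).
#' @param pupil_noise_sd Pupil noise standard deviation.
#' @param pupil_peak Optional `list(time_ms=, amplitude=, width_ms=)`
#'   Gaussian bump added to the pupil series.
#' @return A list with class `event_plan`.
#' @export
#' @examples
#' plan <- event_plan(1000) |>
#'   add_fixation(0, 400, 400, 300) |>
#'   add_saccade(400, 40, 800, 600) |>
#'   add_fixation(440, 500, 800, 600)
event_plan <- function(duration_ms = 2000, start_x = 640, start_y = 512,
                       pupil_baseline = 1000, gaze_noise_sd = 0.005,
                       pupil_noise_sd = 2, pupil_peak = NULL) {
  structure(
    list(
      duration_ms = duration_ms, start_x = start_x, start_y = start_y,
      pupil_baseline = pupil_baseline, gaze_noise_sd = gaze_noise_sd,
      pupil_noise_sd = pupil_noise_sd, pupil_peak = pupil_peak,
      events = tibble(
        kind = character(), onset_ms = numeric(), duration_ms = numeric(),
        x = numeric(), y = numeric(), amplitude = numeric(),
        direction_deg = numeric()
      )
    ),
    class = "event_plan"
  )
}

plan_add <- function(plan, kind, onset_ms, duration_ms, x = NA_real_,
                     y = NA_real_, amplitude = NA_real_,
                     direction_deg = NA_real_) {
  plan$events <- dplyr::bind_rows(plan$events, tibble(
    kind = kind, onset_ms = onset_ms, duration_ms = duration_ms,
    x = x, y = y, amplitude = amplitude, direction_deg = direction_deg
  ))
  plan$events <- dplyr::arrange(plan$events, .data$onset_ms)
  plan
}

#' @rdname event_plan
#' @param plan An `event_plan`.
#' @param onset_ms,duration_ms Event window.
#' @param x,y Fixation centroid or saccade landing point (px).
#' @export
add_fixation <- function(plan, onset_ms, duration_ms, x, y) {
  plan_add(plan, "fixation", onset_ms, duration_ms, x = x, y = y)
}

#' @rdname event_plan
#' @export
add_saccade <- function(plan, onset_ms, duration_ms, x, y) {
  plan_add(plan, "saccade", onset_ms, duration_ms, x = x, y = y)
}

#' @rdname event_plan
#' @param amplitude Microsaccade displacement (px).
#' @param direction_deg Direction of the displacement, degrees.
#' @export
add_microsaccade <- function(plan, onset_ms, duration_ms, amplitude,
                             direction_deg = 45) {
  plan_add(plan, "microsaccade", onset_ms, duration_ms,
           amplitude = amplitude, direction_deg = direction_deg)
}

#' @rdname event_plan
#' @export
add_blink <- function(plan, onset_ms, duration_ms) {
  plan_add(plan, "blink", onset_ms, duration_ms)
}

validate_plan <- function(plan) {
  ev <- plan$events
  if (any(ev$onset_ms < 0) ||
      any(ev$onset_ms + ev$duration_ms > plan$duration_ms)) {
    rlang::abort("planted events must lie within the trial duration")
  }
  host <- ev[ev$kind != "microsaccade", , drop = FALSE]
  if (nrow(host) > 1) {
    host <- host[order(host$onset_ms), , drop = FALSE]
    ends <- host$onset_ms + host$duration_ms
    if (any(host$onset_ms[-1] < ends[-nrow(host)])) {
      rlang::abort("planted events overlap (only microsaccades may nest inside fixations)")
    }
  }
  ms <- ev[ev$kind == "microsaccade", , drop = FALSE]
  fx <- ev[ev$kind == "fixation", , drop = FALSE]
  if (nrow(ms) > 0) {
    nested <- purrr::map_lgl(seq_len(nrow(ms)), function(i) {
      any(fx$onset_ms <= ms$onset_ms[i] &
            fx$onset_ms + fx$duration_ms >= ms$onset_ms[i] + ms$duration_ms[i])
    })
    if (!all(nested)) {
      rlang::abort("every planted microsaccade must nest inside a planted fixation")
    }
  }
  invisible(plan)
}

raised_cosine <- function(u) (1 - cos(pi * u)) / 2

#' Realize a plan into a synthetic trial
#'
#' Deterministic for a given seed. Returns the trial in the base format
#' together with the ground truth: the plan's events with the realized
#' sample indices (`onset_index`, `offset_index`). Blink truth spans the
#' pre-gap descent flank to the post-gap ascent flank; the missing-pupil
#' gap itself contains exactly `duration_ms * sampling_freq / 1000`
#' samples.
#'
#' @param plan An [event_plan()].
#' @param sampling_freq 250, 500 or 1000 Hz.
#' @param seed Integer RNG seed.
#' @param subject_id,stimulus_name Trial labels.
#' @return `list(trial = <tibble>, truth = <tibble>)`.
#' @export
generate_trial <- function(plan, sampling_freq = 1000, seed = 1,
                           subject_id = "s01", stimulus_name = "stim01") {
  if (!sampling_freq %in% c(250, 500, 1000)) {
    rlang::abort("sampling_freq must be one of 250, 500, 1000")
  }
  validate_plan(plan)
  dt <- 1000 / sampling_freq
  n <- as.integer(round(plan$duration_ms / dt)) + 1L
  t <- (seq_len(n) - 1) * dt
  idx_at <- function(ms) as.integer(round(ms / dt)) + 1L

  x <- rep(plan$start_x, n)
  y <- rep(plan$start_y, n)
  ev <- plan$events
  truth <- ev
  truth$onset_index <- NA_integer_
  truth$offset_index <- NA_integer_

  cur_x <- plan$start_x; cur_y <- plan$start_y
  path_events <- which(ev$kind %in% c("fixation", "saccade"))
  last_end <- 0L
  for (i in path_events) {
    i0 <- idx_at(ev$onset_ms[i])
    i1 <- min(n, idx_at(ev$onset_ms[i] + ev$duration_ms[i]))
    if (i0 > last_end + 1L) {
      x[(last_end + 1L):(i0 - 1L)] <- cur_x
      y[(last_end + 1L):(i0 - 1L)] <- cur_y
    }
    span <- i0:i1
    if (ev$kind[i] == "fixation") {
      cur_x <- ev$x[i]; cur_y <- ev$y[i]
      x[span] <- cur_x; y[span] <- cur_y
    } else {
      u <- (span - i0) / max(1L, (i1 - i0))
      x[span] <- cur_x + (ev$x[i] - cur_x) * raised_cosine(u)
      y[span] <- cur_y + (ev$y[i] - cur_y) * raised_cosine(u)
      cur_x <- ev$x[i]; cur_y <- ev$y[i]
    }
    truth$onset_index[i] <- i0
    truth$offset_index[i] <- i1
    last_end <- i1
  }
  if (last_end < n) {
    x[(last_end + 1L):n] <- cur_x
    y[(last_end + 1L):n] <- cur_y
  }

  # microsaccades: raised-cosine displacement held until the host
  # fixation's end (so the excursion itself is the only fast movement)
  for (i in which(ev$kind == "microsaccade")) {
    i0 <- idx_at(ev$onset_ms[i])
    i1 <- min(n, idx_at(ev$onset_ms[i] + ev$duration_ms[i]))
    fx <- ev[ev$kind == "fixation" &
               ev$onset_ms <= ev$onset_ms[i] &
               ev$onset_ms + ev$duration_ms >=
                 ev$onset_ms[i] + ev$duration_ms[i], , drop = FALSE]
    hold_end <- min(n, idx_at(fx$onset_ms[1] + fx$duration_ms[1]))
    theta <- ev$direction_deg[i] * pi / 180
    dx <- ev$amplitude[i] * cos(theta)
    dy <- ev$amplitude[i] * sin(theta)
    span <- i0:i1
    u <- (span - i0) / max(1L, (i1 - i0))
    x[span] <- x[span] + dx * raised_cosine(u)
    y[span] <- y[span] + dy * raised_cosine(u)
    if (hold_end > i1) {
      x[(i1 + 1L):hold_end] <- x[(i1 + 1L):hold_end] + dx
      y[(i1 + 1L):hold_end] <- y[(i1 + 1L):hold_end] + dy
    }
    truth$onset_index[i] <- i0
    truth$offset_index[i] <- i1
  }

  p <- rep(plan$pupil_baseline, n)
  if (!is.null(plan$pupil_peak)) {
    pk <- plan$pupil_peak
    p <- p + pk$amplitude * exp(-0.5 * ((t - pk$time_ms) / pk$width_ms)^2)
  }

  out <- withr::with_seed(as.integer(seed), {
    if (plan$gaze_noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, plan$gaze_noise_sd)
      y <- y + stats::rnorm(n, 0, plan$gaze_noise_sd)
    }
    if (plan$pupil_noise_sd > 0) {
      p <- p + stats::rnorm(n, 0, plan$pupil_noise_sd)
    }
    list(x = x, y = y, p = p)
  })
  x <- out$x; y <- out$y; p <- out$p

  flank_ms <- 20
  for (i in which(ev$kind == "blink")) {
    gap_start <- idx_at(ev$onset_ms[i])
    n_gap <- as.integer(round(ev$duration_ms[i] * sampling_freq / 1000))
    gap <- gap_start:min(n, gap_start + n_gap - 1L)
    n_flank <- max(1L, as.integer(round(flank_ms * sampling_freq / 1000)))
    pre <- max(1L, gap_start - n_flank):(gap_start - 1L)
    post_start <- gap[length(gap)] + 1L
    post <- post_start:min(n, post_start + n_flank - 1L)
    if (gap_start > 1) {
      u <- seq(0, 1, length.out = length(pre) + 1L)[-1]
      p[pre] <- p[pre] * (1 - 0.5 * u)
    }
    if (post_start <= n) {
      u <- seq(0, 1, length.out = length(post) + 1L)[-(length(post) + 1L)]
      p[post] <- p[post] * (0.5 + 0.5 * u)
    }
    p[gap] <- NA_real_
    x[gap] <- NA_real_
    y[gap] <- NA_real_
    truth$onset_index[i] <- max(1L, gap_start - n_flank)
    truth$offset_index[i] <- min(n, post_start + n_flank - 1L)
  }

  samples <- tibble(
    timestamp = t,
    gaze_left_x = x, gaze_left_y = y,
    gaze_right_x = x, gaze_right_y = y,
    pupil_left = p, pupil_right = p,
    event_flag = "none", message = ""
  )
  samples$message[1] <- "stimulus_onset"
  trial <- trial_table(samples, subject_id, stimulus_name, sampling_freq)
  truth$onset_ms_realized <- t[truth$onset_index]
  truth$offset_ms_realized <- t[truth$offset_index]
  list(trial = trial, truth = truth)
}

default_trial_plan <- function(pupil_baseline = 1000, gaze_noise_sd = 0.005,
                               pupil_noise_sd = 2) {
  event_plan(
    duration_ms = 3000, start_x = 300, start_y = 300,
    pupil_baseline = pupil_baseline, gaze_noise_sd = gaze_noise_sd,
    pupil_noise_sd = pupil_noise_sd,
    pupil_peak = list(time_ms = 600, amplitude = 50, width_ms = 150)
  ) |>
    add_fixation(0, 400, 300, 300) |>
    add_saccade(400, 30, 700, 300) |>
    add_fixation(430, 470, 700, 300) |>
    add_saccade(900, 30, 500, 600) |>
    add_fixation(930, 570, 500, 600) |>
    add_microsaccade(1100, 12, amplitude = 12, direction_deg = 45) |>
    add_saccade(1500, 30, 350, 450) |>
    add_fixation(1530, 670, 350, 450) |>
    add_blink(2230, 100) |>
    add_fixation(2360, 540, 350, 450)
}

#' Generate a whole synthetic experiment on disk
#'
#' Writes one base-format CSV per (subject, stimulus) trial under
#' `<out_dir>/base/`, an experiment JSON config at
#' `<out_dir>/experiment.json` (subject groups with Age/Eyesight
#' attributes, grouped stimuli, control list, screen geometry and
#' sampling frequency), and a ground-truth JSON at
#' `<out_dir>/ground_truth.json` recording planted event counts per trial
#' and any injected group effects.
#'
#' Group effects are injected through `effects`; currently
#' `pupil_baseline_delta` adds the given amount to the pupil baseline of
#' every group after the first (a pure between-group pupillometry effect).
#'
#' @param out_dir Output folder (created if needed).
#' @param groups Character vector of subject-group names.
#' @param n_subjects_per_group Subjects per group.
#' @param stimuli_per_group Named list: stimulus-group name -> character
#'   vector of stimulus names.
#' @param control_stimuli Stimulus names to mark as controls (may be
#'   empty).
#' @param seed Integer seed; per-trial seeds are derived deterministically.
#' @param sampling_freq Hz.
#' @param screen `c(width, height)` px.
#' @param effects `list(pupil_baseline_delta = ...)`.
#' @param gaze_noise_sd,pupil_noise_sd Noise levels passed to every trial
#'   plan.
#' @return The experiment config (invisibly), as loaded by
#'   [load_config()].
#' @export
make_synthetic_experiment <- function(out_dir,
                                      groups = c("group1", "group2"),
                                      n_subjects_per_group = 3,
                                      stimuli_per_group = list(
                                        type_A = c("stimA1", "stimA2", "stimA3"),
                                        type_B = c("stimB1", "stimB2", "stimB3")
                                      ),
                                      control_stimuli = character(),
                                      seed = 1,
                                      sampling_freq = 1000,
                                      screen = c(1280, 1024),
                                      effects = list(pupil_baseline_delta = 0),
                                      gaze_noise_sd = 0.005,
                                      pupil_noise_sd = 2) {
  if (length(groups) < 1 || length(stimuli_per_group) < 1) {
    rlang::abort("need at least one subject group and one stimulus group")
  }
  all_stimuli <- unlist(stimuli_per_group, use.names = FALSE)
  if (anyDuplicated(all_stimuli)) rlang::abort("duplicate stimulus names")
  if (!all(control_stimuli %in% all_stimuli)) {
    rlang::abort("control stimuli must be among the stimuli")
  }
  dir.create(file.path(out_dir, "base"), recursive = TRUE, showWarnings = FALSE)

  subjects <- list()
  for (g in seq_along(groups)) {
    nm <- sprintf("s%02d", (g - 1) * n_subjects_per_group + seq_len(n_subjects_per_group))
    subjects[[groups[g]]] <- nm
  }
  all_subjects <- unlist(subjects, use.names = FALSE)
  if (anyDuplicated(all_subjects)) rlang::abort("duplicate subject names across groups")

  delta <- effects$pupil_baseline_delta %||% 0
  trial_counter <- 0L
  truth_records <- list()
  ages <- withr::with_seed(as.integer(seed), sample(20:35, length(all_subjects), replace = TRUE))
  for (g in seq_along(groups)) {
    baseline <- 1000 + if (g > 1) delta else 0
    for (subj in subjects[[groups[g]]]) {
      for (stim in all_stimuli) {
        trial_counter <- trial_counter + 1L
        plan <- default_trial_plan(
          pupil_baseline = baseline,
          gaze_noise_sd = gaze_noise_sd, pupil_noise_sd = pupil_noise_sd
        )
        res <- generate_trial(plan, sampling_freq,
                              seed = as.integer(seed) + trial_counter,
                              subject_id = subj, stimulus_name = stim)
        write_base_csv(res$trial, file.path(out_dir, "base",
                                            paste0(subj, "__", stim, ".csv")))
        counts <- table(factor(res$truth$kind,
                               levels = c("fixation", "saccade", "microsaccade", "blink")))
        truth_records[[trial_counter]] <- c(
          list(subject = subj, stimulus = stim),
          as.list(as.integer(counts)) |> stats::setNames(names(counts))
        )
      }
    }
  }

  config <- list(
    Experiment_name = basename(out_dir),
    Subjects = purrr::imap(subjects, function(nms, grp) {
      purrr::set_names(purrr::map(seq_along(nms), function(i) {
        list(Age = ages[match(nms[i], all_subjects)], Eyesight = "normal")
      }), nms)
    }),
    Stimuli = stimuli_per_group,
    Control = as.list(control_stimuli),
    Analysis_Params = list(
      screen_width = screen[1], screen_height = screen[2],
      sampling_freq = sampling_freq, store_mode = "csv"
    )
  )
  jsonlite::write_json(config, file.path(out_dir, "experiment.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(seed = seed, pupil_baseline_delta = delta, trials = truth_records),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(load_config(file.path(out_dir, "experiment.json")))
}

#' Simulate a null long-format parameter table
#'
#' Draws standard-normal parameter values for a balanced two-group
#' between design crossed with a within factor — no effect anywhere — for
#' calibration studies of the statistical test matrix (type-I error at a
#' chosen alpha).
#'
#' @param n_per_group Subjects per between group.
#' @param n_within Levels of the within factor.
#' @param parameters Parameter names to simulate.
#' @param seed Integer seed.
#' @return A long table as produced by [build_long_table()].
#' @export
simulate_null_long_table <- function(n_per_group = 6, n_within = 2,
                                     parameters = "pupil_mean", seed = 1) {
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grp <- rep(c("group1", "group2"), each = n_per_group)
  wlev <- sprintf("type_%s", LETTERS[seq_len(n_within)])
  grid <- tidyr::expand_grid(
    subject = subj, stimulus_group = wlev, parameter = parameters
  )
  grid$subject_group <- grp[match(grid$subject, subj)]
  grid$stimulus <- paste0(grid$stimulus_group, "_stim")
  withr::with_seed(as.integer(seed), {
    grid$value <- stats::rnorm(nrow(grid))
  })
  grid[, c("subject", "subject_group", "stimulus", "stimulus_group",
           "parameter", "value")]
}
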