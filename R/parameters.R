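#' Names of the 21 extracted eye-movement parameters
#'
#' Four pupillometry, three blink, three fixation, four saccade, four
#' microsaccade and three reading-behaviour scalars per trial, in frozen
#' serialization order.
#'
#' @return Character vector of length 21.
#' @export
eye_parameter_names <- function() {
  c(
    "pupil_mean", "pupil_peak", "pupil_time_to_peak", "pupil_auc",
    "blink_count", "blink_peak_duration", "blink_mean_duration",
    "fixation_count", "fixation_max_duration", "fixation_mean_duration",
    "saccade_count", "saccade_mean_duration", "saccade_mean_velocity",
    "saccade_mean_amplitude",
    "ms_count", "ms_mean_duration", "ms_mean_velocity", "ms_mean_amplitude",
    "reading_count", "first_pass_duration", "second_pass_duration"
  )
}

#' Interpolate pupil size across blinks
#'
#' Replaces each blink window (between its refined onset and offset) and
#' any other lost samples with linear interpolation between the
#' neighbouring valid values; leading and trailing gaps take the nearest
#' valid value. The result has no missing values and equals the raw trace
#' outside blink windows.
#'
#' @param pupil Pupil trace from [pupil_trace()].
#' @param blinks Blink events from [detect_blinks()] (may have zero rows).
#' @return Tibble with columns `t_ms`, `p` (no `NA`).
#' @export
#' @examples
#' tr <- tibble::tibble(t_ms = 0:3, p = c(4, NA, NA, 8))
#' interpolate_pupil(tr, NULL)$p # 4, 5.33, 6.67, 8
interpolate_pupil <- function(pupil, blinks = NULL) {
  p <- pupil$p
  n <- length(p)
  if (!is.null(blinks) && nrow(blinks) > 0) {
    for (i in seq_len(nrow(blinks))) {
      lo <- blinks$onset_index[i]; hi <- blinks$offset_index[i]
      inner <- seq(lo, hi)
      # refined onset/offset are the flanking valid samples; drop everything
      # strictly between them (the occluded flank + the gap)
      inner <- inner[inner > lo & inner < hi]
      p[inner] <- NA_real_
    }
  }
  valid <- which(!is.na(p))
  if (length(valid) == 0) rlang::abort("pupil trace has no valid samples to interpolate from")
  filled <- stats::approx(
    x = pupil$t_ms[valid], y = p[valid], xout = pupil$t_ms,
    method = "linear", rule = 2
  )$y
  tibble(t_ms = pupil$t_ms, p = filled)
}

#' Pupillometry parameters
#'
#' Over the post-onset part of the interpolated trace: mean pupil size,
#' peak (maximum) size, time to peak in ms (time of the first maximum
#' minus onset), and area under the curve by trapezoidal integration
#' (pupil units x ms).
#'
#' @param trace Interpolated pupil trace ([interpolate_pupil()]).
#' @param onset_ms Analysis-window onset (default: trace start).
#' @return Named list of 4 scalars.
#' @export
pupil_parameters <- function(trace, onset_ms = NULL) {
  if (nrow(trace) == 0) rlang::abort("empty pupil trace")
  onset_ms <- onset_ms %||% trace$t_ms[1]
  if (onset_ms > trace$t_ms[nrow(trace)]) {
    rlang::abort("onset_ms is after the end of the trace")
  }
  post <- trace[trace$t_ms >= onset_ms, ]
  peak_idx <- which.max(post$p)
  auc <- if (nrow(post) > 1) pracma::trapz(post$t_ms, post$p) else 0
  list(
    pupil_mean = mean(post$p),
    pupil_peak = max(post$p),
    pupil_time_to_peak = post$t_ms[peak_idx] - onset_ms,
    pupil_auc = auc
  )
}

#' Aggregate event-family parameters
#'
#' Counts and duration/velocity/amplitude aggregates for blinks,
#' fixations, saccades and microsaccades. If an AOI is given, the
#' fixation family is restricted to fixations whose centroid lies inside
#' it. Empty families report count 0 and zero aggregates.
#'
#' @param events `gaze_events` tibble holding any mix of kinds.
#' @param aoi Optional `aoi_spec` conditioning the fixation family.
#' @return Named list of 14 scalars.
#' @export
aggregate_event_parameters <- function(events, aoi = NULL) {
  fam <- function(kind) events[events$kind == kind, , drop = FALSE]
  blinks <- fam("blink")
  fixations <- fam("fixation")
  if (!is.null(aoi) && nrow(fixations) > 0) {
    keep <- contains_point(aoi, fixations$x, fixations$y)
    fixations <- fixations[keep, , drop = FALSE]
  }
  saccades <- fam("saccade")
  micro <- fam("microsaccade")
  mean0 <- function(v) if (length(v) == 0) 0 else mean(v)
  max0 <- function(v) if (length(v) == 0) 0 else max(v)
  list(
    blink_count = nrow(blinks),
    blink_peak_duration = max0(blinks$duration_ms),
    blink_mean_duration = mean0(blinks$duration_ms),
    fixation_count = nrow(fixations),
    fixation_max_duration = max0(fixations$duration_ms),
    fixation_mean_duration = mean0(fixations$duration_ms),
    saccade_count = nrow(saccades),
    saccade_mean_duration = mean0(saccades$duration_ms),
    saccade_mean_velocity = mean0(saccades$peak_velocity),
    saccade_mean_amplitude = mean0(saccades$amplitude),
    ms_count = nrow(micro),
    ms_mean_duration = mean0(micro$duration_ms),
    ms_mean_velocity = mean0(micro$peak_velocity),
    ms_mean_amplitude = mean0(micro$amplitude)
  )
}

#' Reading-behaviour parameters
#'
#' A *reading* is a maximal run of consecutive fixations whose centroids
#' lie inside the AOI. Reported are the number of readings and the summed
#' fixation durations of the first and second runs (first/second pass;
#' zero when absent).
#'
#' @param fixations Time-ordered fixation events.
#' @param aoi An `aoi_spec` (required).
#' @return Named list of 3 scalars.
#' @export
reading_parameters <- function(fixations, aoi) {
  if (is.null(aoi)) rlang::abort("reading parameters require an AOI")
  if (nrow(fixations) == 0) {
    return(list(reading_count = 0, first_pass_duration = 0, second_pass_duration = 0))
  }
  fixations <- fixations[order(fixations$onset_ms), , drop = FALSE]
  inside <- contains_point(aoi, fixations$x, fixations$y)
  runs <- valid_runs(inside)
  pass_dur <- function(i) {
    if (length(runs) < i) 0 else sum(fixations$duration_ms[runs[[i]]])
  }
  list(
    reading_count = length(runs),
    first_pass_duration = pass_dur(1),
    second_pass_duration = pass_dur(2)
  )
}

#' Extract the 21-parameter set for one trial
#'
#' Runs the whole per-trial pipeline: blink detection on the pupil trace,
#' blink masking of the gaze trace, I-DT fixations, I-VT saccades,
#' per-fixation microsaccades, pupil interpolation, and all aggregates.
#' With no AOI the reading parameters are zero (no region to read).
#'
#' The pupil analysis window starts at the stimulus-onset message when one
#' is present (a sample whose `message` contains "onset"), else at the
#' first sample.
#'
#' @param trial Base-format trial tibble.
#' @param cfg A [detection_config()].
#' @param aoi Optional `aoi_spec`.
#' @return One-row tibble: `subject_id`, `stimulus_name`, then the 21
#'   parameters of [eye_parameter_names()] in order.
#' @export
extract_parameter_set <- function(trial, cfg = detection_config(), aoi = NULL) {
  trial <- validate_trial_table(trial)
  pupil <- pupil_trace(trial, eye = cfg$eye)
  blinks <- detect_blinks(pupil, cfg)
  gaze <- gaze_trace(trial, eye = cfg$eye, mask_events = blinks)
  fixations <- detect_fixations_idt(gaze, cfg)
  saccades <- detect_saccades_ivt(gaze, cfg)
  micro <- purrr::map(seq_len(nrow(fixations)), function(i) {
    idx <- seq(fixations$onset_index[i], fixations$offset_index[i])
    seg <- gaze[idx, ]
    attr(seg, "sampling_freq") <- attr(gaze, "sampling_freq")
    detect_microsaccades(seg, cfg)
  })
  events <- dplyr::bind_rows(blinks, fixations, saccades, dplyr::bind_rows(micro))

  onset_ms <- NULL
  hit <- which(stringr::str_detect(trial$message, stringr::fixed("onset")))
  if (length(hit) > 0) onset_ms <- trial$timestamp[hit[1]]
  interp <- interpolate_pupil(pupil, blinks)
  pupil_pars <- pupil_parameters(interp, onset_ms)

  event_pars <- aggregate_event_parameters(events, aoi)
  reading_pars <- if (is.null(aoi)) {
    list(reading_count = 0, first_pass_duration = 0, second_pass_duration = 0)
  } else {
    reading_parameters(events[events$kind == "fixation", , drop = FALSE], aoi)
  }

  out <- c(
    list(subject_id = trial$subject_id[1], stimulus_name = trial$stimulus_name[1]),
    pupil_pars, event_pars, reading_pars
  )
  as_tibble(out)[, c("subject_id", "stimulus_name", eye_parameter_names())]
}

#' Normalize parameters against control stimuli
#'
#' For every subject and every parameter, the mean value over that
#' subject's control trials is the baseline: with `method = "subtract"`
#' (default) it is subtracted from each non-control trial's value; with
#' `method = "ratio"` each value is divided by it. Control trials are
#' dropped from the output.
#'
#' @param sets Parameter-set tibble (rows from [extract_parameter_set()]).
#' @param control_stimuli Character vector of control stimulus names.
#' @param method `"subtract"` or `"ratio"`.
#' @return Tibble of normalized non-control rows.
#' @export
normalize_with_controls <- function(sets, control_stimuli,
                                    method = c("subtract", "ratio")) {
  method <- match.arg(method)
  if (length(control_stimuli) == 0) rlang::abort("no control stimuli given")
  is_control <- sets$stimulus_name %in% control_stimuli
  subjects <- unique(sets$subject_id)
  missing <- subjects[!subjects %in% unique(sets$subject_id[is_control])]
  if (length(missing) > 0) {
    rlang::abort(paste0("subject(s) without any control trial: ",
                        paste(missing, collapse = ", ")))
  }
  if (all(is_control)) {
    rlang::warn("all trials are controls; nothing to normalize")
    return(sets[0, , drop = FALSE])
  }
  baselines <- sets |>
    dplyr::filter(is_control) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(eye_parameter_names()), mean),
                     .groups = "drop")
  out <- sets[!is_control, , drop = FALSE]
  for (subj in unique(out$subject_id)) {
    base <- baselines[baselines$subject_id == subj, eye_parameter_names()]
    rows <- out$subject_id == subj
    vals <- out[rows, eye_parameter_names()]
    out[rows, eye_parameter_names()] <- if (method == "subtract") {
      sweep(as.matrix(vals), 2, as.numeric(base), "-")
    } else {
      sweep(as.matrix(vals), 2, as.numeric(base), "/")
    }
  }
  out
}

#' Write detected events to CSV
#'
#' One row per event: kind, onset/offset (index and ms), duration, and
#' the kind-specific centroid, peak velocity and amplitude columns.
#'
#' @param events `gaze_events` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(as_tibble(events), path, na = "")
  invisible(path)
}
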