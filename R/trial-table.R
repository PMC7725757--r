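#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate arrange select group_by ungroup summarise
#'   bind_rows across all_of n
#' @importFrom tibble tibble as_tibble is_tibble
NULL

#' Column schema of the base trial-table format
#'
#' Every vendor export is converted to one flat, comma-separated table per
#' trial with exactly these columns, in this order. The schema is frozen:
#' `subject_id` and `stimulus_name` label the trial, `timestamp` is in
#' milliseconds since recording start, gaze coordinates are screen pixels
#' (origin top-left, y increasing downward), pupil sizes are vendor
#' arbitrary units, `event_flag` is one of `none`, `fixation`, `saccade`,
#' `blink` as marked by the recording software, `message` is free text
#' (empty string when absent) and `sampling_freq` is the nominal sampling
#' rate in Hz (constant within a trial). Lost samples are encoded as `NA`
#' in the pupil columns; gaze may be `NA` only where pupil is `NA`.
#'
#' @return Character vector of column names.
#' @export
#' @examples
#' base_format_columns()
base_format_columns <- function() {
  c(
    "subject_id", "stimulus_name", "timestamp",
    "gaze_left_x", "gaze_left_y", "gaze_right_x", "gaze_right_y",
    "pupil_left", "pupil_right", "event_flag", "message", "sampling_freq"
  )
}

base_numeric_columns <- function() {
  c(
    "timestamp", "gaze_left_x", "gaze_left_y", "gaze_right_x",
    "gaze_right_y", "pupil_left", "pupil_right", "sampling_freq"
  )
}

event_flag_levels <- function() c("none", "fixation", "saccade", "blink")

#' Build a validated trial table
#'
#' Assembles per-sample recordings into the base trial-table format and
#' checks its invariants: non-empty, strictly increasing timestamps,
#' non-negative pupil sizes, and gaze missing only where pupil is missing.
#' A timestamp violation is an error, never a silent reorder.
#'
#' @param samples Data frame with at least `timestamp`; missing gaze/pupil
#'   columns are filled with the right eye mirrored, `NA`, or defaults.
#' @param subject_id,stimulus_name Trial labels.
#' @param sampling_freq Sampling rate in Hz.
#' @return A tibble in the base format (one row per sample).
#' @export
trial_table <- function(samples, subject_id, stimulus_name, sampling_freq) {
  samples <- as_tibble(samples)
  if (nrow(samples) == 0) abort("trial table must contain at least one sample")
  if (!"timestamp" %in% names(samples)) abort("samples must contain `timestamp`")
  for (col in c("gaze_left_x", "gaze_left_y", "gaze_right_x", "gaze_right_y",
                "pupil_left", "pupil_right")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_real_
  }
  if (!"event_flag" %in% names(samples)) samples$event_flag <- "none"
  if (!"message" %in% names(samples)) samples$message <- ""
  samples$subject_id <- as.character(subject_id)
  samples$stimulus_name <- as.character(stimulus_name)
  samples$sampling_freq <- as.numeric(sampling_freq)
  out <- samples[, base_format_columns()]
  out$message[is.na(out$message)] <- ""
  out$event_flag[is.na(out$event_flag)] <- "none"
  validate_trial_table(out)
}

#' Validate a base-format trial table
#'
#' @param trial A tibble in the base format.
#' @return The trial, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_trial_table <- function(trial) {
  trial <- as_tibble(trial)
  missing_cols <- setdiff(base_format_columns(), names(trial))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trial) == 0) abort("trial table must contain at least one sample")
  if (anyNA(trial$timestamp)) abort("timestamps must not be missing")
  if (any(diff(trial$timestamp) <= 0)) {
    bad <- which(diff(trial$timestamp) <= 0)[1] + 1
    abort(paste0("timestamps must be strictly increasing (violated at sample ",
                 bad, ")"))
  }
  for (col in c("pupil_left", "pupil_right")) {
    if (any(trial[[col]] < 0, na.rm = TRUE)) {
      abort(paste0(col, " must be >= 0 (0/NA encode a lost sample)"))
    }
  }
  bad_flags <- setdiff(unique(trial$event_flag), event_flag_levels())
  if (length(bad_flags) > 0) {
    abort(paste0("unknown event_flag value(s): ", paste(bad_flags, collapse = ", ")))
  }
  # gaze may be missing only where the same eye's pupil is missing
  for (eye in c("left", "right")) {
    gx <- trial[[paste0("gaze_", eye, "_x")]]
    gy <- trial[[paste0("gaze_", eye, "_y")]]
    p <- trial[[paste0("pupil_", eye)]]
    lost <- is.na(p) | (!is.na(p) & p == 0)
    if (any((is.na(gx) | is.na(gy)) & !lost)) {
      abort(paste0(eye, " gaze is missing on a sample with a valid pupil"))
    }
  }
  if (length(unique(trial$subject_id)) != 1 ||
      length(unique(trial$stimulus_name)) != 1) {
    abort("a trial table holds exactly one (subject, stimulus) pair")
  }
  sf <- unique(trial$sampling_freq)
  if (length(sf) != 1 || is.na(sf) || sf <= 0) {
    abort("sampling_freq must be a single positive value")
  }
  trial
}

trial_sampling_freq <- function(trial) trial$sampling_freq[1]

#' Write / read one trial in the base CSV format
#'
#' Plain UTF-8 CSV, one header row, comma separator, columns exactly as
#' [base_format_columns()]. Missing values are empty fields.
#'
#' @param trial Base-format trial tibble.
#' @param path File path.
#' @return `write_base_csv()` returns `path` invisibly; `read_base_csv()`
#'   returns the validated trial tibble.
#' @export
write_base_csv <- function(trial, path) {
  validate_trial_table(trial)
  readr::write_csv(trial, path, na = "")
  invisible(path)
}

#' @rdname write_base_csv
#' @export
read_base_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  trial <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      stimulus_name = readr::col_character(),
      event_flag = readr::col_character(),
      message = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(base_format_columns(), names(trial))
  if (length(missing_cols) > 0) {
    abort(paste0("malformed base CSV ", path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  trial$message[is.na(trial$message)] <- ""
  trial$event_flag[is.na(trial$event_flag)] <- "none"
  validate_trial_table(trial[, base_format_columns()])
}
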