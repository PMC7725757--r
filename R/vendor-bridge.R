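#' Convert a vendor text export to base-format trials
#'
#' Parses one of three documented text dialects and returns one validated
#' base-format trial per recorded trial. No dialect sniffing is done; the
#' vendor must be declared.
#'
#' @section Dialect grammars:
#' **eyelink** (ASC-style). Header comment lines start with `**` and carry
#' `** RATE <hz>` and `** SUBJECT <id>`. Each trial is bracketed by
#' `START <t>` / `END <t>` lines. `MSG <t> TRIALID <stimulus>` names the
#' trial; other `MSG <t> <text>` lines attach `<text>` to the sample with
#' timestamp `<t>`. Sample lines are tab-separated
#' `<t> <lx> <ly> <lp> <rx> <ry> <rp> <flag>` with `.` for lost values.
#'
#' **smi** (BeGaze-style text). `##` comment header with
#' `## Sample Rate: <hz>` and `## Subject: <id>`; then a tab-separated
#' header row and one row per record:
#' `Time Type Trial L POR X [px] L POR Y [px] R POR X [px] R POR Y [px]
#' L Pupil R Pupil Event`. `Type` is `SMP` for samples and `MSG` for
#' messages, whose text follows `# Message: `. The first message of a
#' trial names the stimulus. Lost samples carry pupil `0` (gaze fields
#' then ignored). The `Trial` column delimits trials.
#'
#' **tobii** (TSV). One quoted-TSV header row with columns
#' `Recording timestamp`, `Participant name`, `Presented Stimulus name`,
#' `Gaze point left X/Y`, `Gaze point right X/Y`,
#' `Pupil diameter left/right`, `Eye movement type`, `Event`. Lost values
#' are empty cells; a change in `Presented Stimulus name` starts a new
#' trial; the sampling rate is inferred from the median timestamp step.
#'
#' @param path Vendor file path.
#' @param vendor `"eyelink"`, `"smi"` or `"tobii"`.
#' @return List of base-format trial tibbles.
#' @export
convert_vendor_export <- function(path, vendor = c("eyelink", "smi", "tobii")) {
  if (!is.character(vendor) || length(vendor) != 1 ||
      !vendor %in% c("eyelink", "smi", "tobii")) {
    rlang::abort(paste0("unknown vendor tag: ", paste(vendor, collapse = "/")))
  }
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  trials <- switch(vendor,
    eyelink = parse_eyelink(path),
    smi = parse_smi(path),
    tobii = parse_tobii(path)
  )
  if (length(trials) == 0) {
    rlang::abort(paste0("parse error in ", path, ": no trials found"))
  }
  trials
}

num_or_na <- function(x, sentinel = ".") {
  x[x == sentinel | x == ""] <- NA
  suppressWarnings(as.numeric(x))
}

finish_trial <- function(samples, subject, stimulus, sfreq, path, line_no) {
  tryCatch(
    trial_table(samples, subject, stimulus, sfreq),
    error = function(e) {
      rlang::abort(paste0("parse error in ", path, " near line ", line_no,
                          ": ", conditionMessage(e)))
    }
  )
}

parse_eyelink <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sfreq <- NA_real_
  subject <- "unknown"
  trials <- list()
  cur <- NULL # list of sample rows
  cur_msgs <- list() # timestamp -> message
  stimulus <- NA_character_
  flag_map <- c(`.` = "none", FIX = "fixation", SACC = "saccade", BLINK = "blink")
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "" || grepl("^\\s*$", line)) next
    if (startsWith(line, "**")) {
      m <- stringr::str_match(line, "^\\*\\*\\s+RATE\\s+(\\S+)")
      if (!is.na(m[1, 2])) sfreq <- as.numeric(m[1, 2])
      m <- stringr::str_match(line, "^\\*\\*\\s+SUBJECT\\s+(.+)$")
      if (!is.na(m[1, 2])) subject <- m[1, 2]
      next
    }
    if (startsWith(line, "START")) {
      cur <- list(); cur_msgs <- list(); stimulus <- NA_character_
      next
    }
    if (startsWith(line, "END")) {
      if (is.null(cur) || length(cur) == 0) {
        rlang::abort(paste0("parse error in ", path, " at line ", ln,
                            ": END with no samples"))
      }
      samples <- dplyr::bind_rows(cur)
      for (ts in names(cur_msgs)) {
        hit <- which(samples$timestamp == as.numeric(ts))
        if (length(hit) > 0) samples$message[hit[1]] <- cur_msgs[[ts]]
      }
      trials[[length(trials) + 1]] <- finish_trial(
        samples, subject,
        if (is.na(stimulus)) paste0("trial", length(trials) + 1) else stimulus,
        sfreq, path, ln
      )
      cur <- NULL
      next
    }
    if (startsWith(line, "MSG")) {
      m <- stringr::str_match(line, "^MSG\\t([0-9.]+)\\t(.*)$")
      if (is.na(m[1, 1])) {
        rlang::abort(paste0("parse error in ", path, " at line ", ln,
                            ": malformed MSG line"))
      }
      txt <- m[1, 3]
      tid <- stringr::str_match(txt, "^TRIALID\\s+(.+)$")
      if (!is.na(tid[1, 2])) {
        stimulus <- tid[1, 2]
      } else {
        cur_msgs[[m[1, 2]]] <- txt
      }
      next
    }
    if (is.null(cur)) next # samples outside START/END are ignored
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 8) {
      rlang::abort(paste0("parse error in ", path, " at line ", ln,
                          ": expected 8 tab-separated fields, got ", length(parts)))
    }
    cur[[length(cur) + 1]] <- tibble(
      timestamp = num_or_na(parts[1]),
      gaze_left_x = num_or_na(parts[2]), gaze_left_y = num_or_na(parts[3]),
      pupil_left = num_or_na(parts[4]),
      gaze_right_x = num_or_na(parts[5]), gaze_right_y = num_or_na(parts[6]),
      pupil_right = num_or_na(parts[7]),
      event_flag = {fl <- unname(flag_map[parts[8]]); if (is.na(fl)) "none" else fl},
      message = ""
    )
  }
  trials
}

parse_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sfreq <- NA_real_
  subject <- "unknown"
  header_seen <- FALSE
  flag_map <- c(`-` = "none", Fixation = "fixation", Saccade = "saccade",
                Blink = "blink")
  trial_ids <- character()
  rows <- list()
  msgs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "") next
    if (startsWith(line, "##")) {
      m <- stringr::str_match(line, "^##\\s*Sample Rate:\\s*(\\S+)")
      if (!is.na(m[1, 2])) sfreq <- as.numeric(m[1, 2])
      m <- stringr::str_match(line, "^##\\s*Subject:\\s*(.+)$")
      if (!is.na(m[1, 2])) subject <- m[1, 2]
      next
    }
    if (!header_seen) { header_seen <- TRUE; next } # the column header row
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      rlang::abort(paste0("parse error in ", path, " at line ", ln,
                          ": expected tab-separated record"))
    }
    trial_id <- parts[3]
    if (parts[2] == "MSG") {
      txt <- stringr::str_match(paste(parts[-(1:3)], collapse = "\t"),
                                "^# Message: (.*)$")[1, 2]
      if (is.na(txt)) {
        rlang::abort(paste0("parse error in ", path, " at line ", ln,
                            ": malformed SMI message"))
      }
      msgs[[trial_id]] <- c(msgs[[trial_id]],
                            stats::setNames(txt, parts[1]))
      next
    }
    if (parts[2] != "SMP") {
      rlang::abort(paste0("parse error in ", path, " at line ", ln,
                          ": unknown record type '", parts[2], "'"))
    }
    if (length(parts) < 10) {
      rlang::abort(paste0("parse error in ", path, " at line ", ln,
                          ": expected 10 fields in SMP record"))
    }
    lp <- num_or_na(parts[8], "0.00"); rp <- num_or_na(parts[9], "0.00")
    lp <- ifelse(!is.na(lp) & lp == 0, NA_real_, lp)
    rp <- ifelse(!is.na(rp) & rp == 0, NA_real_, rp)
    rows[[length(rows) + 1]] <- tibble(
      trial_id = trial_id,
      timestamp = num_or_na(parts[1]),
      gaze_left_x = if (is.na(lp)) NA_real_ else num_or_na(parts[4]),
      gaze_left_y = if (is.na(lp)) NA_real_ else num_or_na(parts[5]),
      gaze_right_x = if (is.na(rp)) NA_real_ else num_or_na(parts[6]),
      gaze_right_y = if (is.na(rp)) NA_real_ else num_or_na(parts[7]),
      pupil_left = lp, pupil_right = rp,
      event_flag = {fl <- unname(flag_map[parts[10]]); if (is.na(fl)) "none" else fl},
      message = ""
    )
    if (!trial_id %in% trial_ids) trial_ids <- c(trial_ids, trial_id)
  }
  if (length(rows) == 0) return(list())
  all_rows <- dplyr::bind_rows(rows)
  purrr::map(trial_ids, function(tid) {
    samples <- all_rows[all_rows$trial_id == tid, , drop = FALSE]
    samples$trial_id <- NULL
    stimulus <- paste0("trial", tid)
    for (i in seq_along(msgs[[tid]])) {
      txt <- msgs[[tid]][i]
      ts <- as.numeric(names(msgs[[tid]])[i])
      stim_m <- stringr::str_match(txt, "^STIMULUS: (.+)$")
      if (!is.na(stim_m[1, 2])) {
        stimulus <- stim_m[1, 2]
      } else {
        hit <- which(samples$timestamp == ts)
        if (length(hit) > 0) samples$message[hit[1]] <- unname(txt)
      }
    }
    finish_trial(samples, subject, stimulus, sfreq, path, NA)
  })
}

tobii_columns <- function() {
  c("Recording timestamp", "Participant name", "Presented Stimulus name",
    "Gaze point left X", "Gaze point left Y", "Gaze point right X",
    "Gaze point right Y", "Pupil diameter left", "Pupil diameter right",
    "Eye movement type", "Event")
}

parse_tobii <- function(path) {
  tab <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = character()),
    error = function(e) {
      rlang::abort(paste0("parse error in ", path, " at line 1: ",
                          conditionMessage(e)))
    }
  )
  if (nrow(tab) == 0) return(list())
  missing_cols <- setdiff(tobii_columns(), names(tab))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("parse error in ", path, " at line 1: missing column(s) ",
                        paste(missing_cols, collapse = ", ")))
  }
  flag_map <- c(Unclassified = "none", Fixation = "fixation",
                Saccade = "saccade", Blink = "blink")
  ts <- num_or_na(tab[["Recording timestamp"]], "")
  stim <- tab[["Presented Stimulus name"]]
  sfreq <- round(1000 / stats::median(diff(ts)))
  block <- cumsum(c(TRUE, stim[-1] != stim[-length(stim)]))
  purrr::map(unique(block), function(b) {
    rows <- which(block == b)
    samples <- tibble(
      timestamp = ts[rows],
      gaze_left_x = num_or_na(tab[["Gaze point left X"]][rows], ""),
      gaze_left_y = num_or_na(tab[["Gaze point left Y"]][rows], ""),
      gaze_right_x = num_or_na(tab[["Gaze point right X"]][rows], ""),
      gaze_right_y = num_or_na(tab[["Gaze point right Y"]][rows], ""),
      pupil_left = num_or_na(tab[["Pupil diameter left"]][rows], ""),
      pupil_right = num_or_na(tab[["Pupil diameter right"]][rows], ""),
      event_flag = unname(flag_map[tab[["Eye movement type"]][rows]] %||% "none"),
      message = tab[["Event"]][rows]
    )
    samples$event_flag[is.na(samples$event_flag)] <- "none"
    finish_trial(samples, tab[["Participant name"]][rows[1]], stim[rows[1]],
                 sfreq, path, rows[1] + 1)
  })
}

#' Write a trial in a vendor text dialect
#'
#' The inverse of [convert_vendor_export()]: emits a file in the chosen
#' dialect (grammars documented there) that parses back to the same
#' samples, flags and messages. Useful for exercising the format bridge
#' without recorded data.
#'
#' @param trial Base-format trial tibble (or list of them, written to one
#'   file as consecutive trials).
#' @param vendor `"eyelink"`, `"smi"` or `"tobii"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vendor_export <- function(trial, vendor = c("eyelink", "smi", "tobii"),
                                path) {
  vendor <- match.arg(vendor)
  trials <- if (is_tibble(trial)) list(trial) else trial
  purrr::walk(trials, validate_trial_table)
  if (any(purrr::map_int(trials, nrow) == 0)) {
    rlang::abort("refusing to write a trial with no samples")
  }
  switch(vendor,
    eyelink = write_eyelink(trials, path),
    smi = write_smi(trials, path),
    tobii = write_tobii(trials, path)
  )
  invisible(path)
}

fmt_num <- function(x, sentinel = ".") {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- sentinel
  out
}

write_eyelink <- function(trials, path) {
  flag_map <- c(none = ".", fixation = "FIX", saccade = "SACC", blink = "BLINK")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "** EYE-TRACKER ASCII EXPORT",
    paste0("** RATE ", fmt_num(trials[[1]]$sampling_freq[1])),
    paste0("** SUBJECT ", trials[[1]]$subject_id[1])
  ), con)
  for (trial in trials) {
    writeLines(paste0("START\t", fmt_num(trial$timestamp[1])), con)
    writeLines(paste0("MSG\t", fmt_num(trial$timestamp[1]),
                      "\tTRIALID ", trial$stimulus_name[1]), con)
    for (i in seq_len(nrow(trial))) {
      if (trial$message[i] != "") {
        writeLines(paste0("MSG\t", fmt_num(trial$timestamp[i]), "\t",
                          trial$message[i]), con)
      }
      writeLines(paste(
        fmt_num(trial$timestamp[i]),
        fmt_num(trial$gaze_left_x[i]), fmt_num(trial$gaze_left_y[i]),
        fmt_num(trial$pupil_left[i]),
        fmt_num(trial$gaze_right_x[i]), fmt_num(trial$gaze_right_y[i]),
        fmt_num(trial$pupil_right[i]),
        flag_map[[trial$event_flag[i]]],
        sep = "\t"
      ), con)
    }
    writeLines(paste0("END\t", fmt_num(trial$timestamp[nrow(trial)])), con)
  }
}

write_smi <- function(trials, path) {
  flag_map <- c(none = "-", fixation = "Fixation", saccade = "Saccade",
                blink = "Blink")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "## [Text Export]",
    paste0("## Sample Rate: ", fmt_num(trials[[1]]$sampling_freq[1])),
    paste0("## Subject: ", trials[[1]]$subject_id[1]),
    paste("Time", "Type", "Trial", "L POR X [px]", "L POR Y [px]",
          "R POR X [px]", "R POR Y [px]", "L Pupil", "R Pupil", "Event",
          sep = "\t")
  ), con)
  for (k in seq_along(trials)) {
    trial <- trials[[k]]
    writeLines(paste(fmt_num(trial$timestamp[1]), "MSG", k,
                     paste0("# Message: STIMULUS: ", trial$stimulus_name[1]),
                     sep = "\t"), con)
    for (i in seq_len(nrow(trial))) {
      if (trial$message[i] != "") {
        writeLines(paste(fmt_num(trial$timestamp[i]), "MSG", k,
                         paste0("# Message: ", trial$message[i]),
                         sep = "\t"), con)
      }
      writeLines(paste(
        fmt_num(trial$timestamp[i]), "SMP", k,
        fmt_num(trial$gaze_left_x[i], "0"), fmt_num(trial$gaze_left_y[i], "0"),
        fmt_num(trial$gaze_right_x[i], "0"), fmt_num(trial$gaze_right_y[i], "0"),
        fmt_num(trial$pupil_left[i], "0"), fmt_num(trial$pupil_right[i], "0"),
        flag_map[[trial$event_flag[i]]],
        sep = "\t"
      ), con)
    }
  }
}

write_tobii <- function(trials, path) {
  flag_map <- c(none = "Unclassified", fixation = "Fixation",
                saccade = "Saccade", blink = "Blink")
  tab <- dplyr::bind_rows(purrr::map(trials, function(trial) {
    tibble(
      `Recording timestamp` = fmt_num(trial$timestamp, ""),
      `Participant name` = trial$subject_id,
      `Presented Stimulus name` = trial$stimulus_name,
      `Gaze point left X` = fmt_num(trial$gaze_left_x, ""),
      `Gaze point left Y` = fmt_num(trial$gaze_left_y, ""),
      `Gaze point right X` = fmt_num(trial$gaze_right_x, ""),
      `Gaze point right Y` = fmt_num(trial$gaze_right_y, ""),
      `Pupil diameter left` = fmt_num(trial$pupil_left, ""),
      `Pupil diameter right` = fmt_num(trial$pupil_right, ""),
      `Eye movement type` = unname(flag_map[trial$event_flag]),
      Event = trial$message
    )
  }))
  readr::write_tsv(tab, path, quote = "needed", escape = "double", na = "")
}
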