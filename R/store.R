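#' Aggregate base-format trials into a queryable store
#'
#' Indexes every base CSV in a folder over (subject, stimulus). With
#' `mode = "csv"` trials stay in their per-trial files and queries read
#' the matching files; with `mode = "sql"` all samples are aggregated
#' into a single-file SQLite database (one `samples` table, indexed on
#' subject and stimulus) and queries run as conditional SQL. Both modes
#' return identical query results.
#'
#' @param csv_dir Folder containing at least one base-format CSV.
#' @param mode `"csv"` or `"sql"`.
#' @param db_path SQLite file path for `mode = "sql"` (default
#'   `<csv_dir>/experiment.sqlite`).
#' @return A list with class `experiment_store`.
#' @export
build_store <- function(csv_dir, mode = c("csv", "sql"), db_path = NULL) {
  mode <- match.arg(mode)
  files <- sort(list.files(csv_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    rlang::abort(paste0("no base-format CSV files found in ", csv_dir))
  }
  trials <- purrr::map(files, read_base_csv)
  index <- tibble(
    subject_id = purrr::map_chr(trials, ~ .x$subject_id[1]),
    stimulus_name = purrr::map_chr(trials, ~ .x$stimulus_name[1]),
    file = files
  )
  if (anyDuplicated(index[, c("subject_id", "stimulus_name")])) {
    rlang::abort("duplicate (subject, stimulus) trials in folder")
  }
  store <- list(mode = mode, dir = csv_dir, index = index, db_path = NULL)
  if (mode == "sql") {
    db_path <- db_path %||% file.path(csv_dir, "experiment.sqlite")
    if (file.exists(db_path)) unlink(db_path)
    con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbWriteTable(con, "samples", dplyr::bind_rows(trials))
    DBI::dbExecute(con, "CREATE INDEX idx_subj_stim ON samples (subject_id, stimulus_name)")
    store$db_path <- db_path
  }
  structure(store, class = "experiment_store")
}

#' @export
print.experiment_store <- function(x, ...) {
  cat("<experiment_store>", x$mode, "backing,", nrow(x$index), "trial(s)\n")
  invisible(x)
}

#' Query trials from a store
#'
#' Returns exactly the trials whose subject and stimulus match, ordered
#' by subject then stimulus (lexicographic). Requested names absent from
#' the store produce a warning, never an error.
#'
#' @param store An [build_store()] result.
#' @param subjects Character vector of subject names, or `"all"`.
#' @param stimuli Character vector of stimulus names, or `"all"`.
#' @return List of base-format trial tibbles (possibly empty).
#' @export
query_trials <- function(store, subjects = "all", stimuli = "all") {
  if (!inherits(store, "experiment_store")) {
    rlang::abort("`store` must come from build_store()")
  }
  idx <- store$index
  if (!identical(subjects, "all")) {
    ghost <- setdiff(subjects, idx$subject_id)
    if (length(ghost) > 0) {
      rlang::warn(paste0("unknown subject(s): ", paste(ghost, collapse = ", ")))
    }
    idx <- idx[idx$subject_id %in% subjects, , drop = FALSE]
  }
  if (!identical(stimuli, "all")) {
    ghost <- setdiff(stimuli, store$index$stimulus_name)
    if (length(ghost) > 0) {
      rlang::warn(paste0("unknown stimulus(-i): ", paste(ghost, collapse = ", ")))
    }
    idx <- idx[idx$stimulus_name %in% stimuli, , drop = FALSE]
  }
  idx <- idx[order(idx$subject_id, idx$stimulus_name), , drop = FALSE]
  if (nrow(idx) == 0) return(list())
  if (store$mode == "csv") {
    purrr::map(idx$file, read_base_csv)
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), store$db_path)
    on.exit(DBI::dbDisconnect(con))
    purrr::map(seq_len(nrow(idx)), function(i) {
      rows <- DBI::dbGetQuery(
        con,
        "SELECT * FROM samples WHERE subject_id = ? AND stimulus_name = ? ORDER BY timestamp",
        params = list(idx$subject_id[i], idx$stimulus_name[i])
      )
      validate_trial_table(as_tibble(rows)[, base_format_columns()])
    })
  }
}
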