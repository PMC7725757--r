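#' Load and validate an experiment JSON config
#'
#' The config drives whole-experiment analysis. Canonical schema (the
#' reader also accepts lower-case key spellings):
#'
#' ```json
#' {
#'   "Experiment_name": "demo",
#'   "Subjects": {
#'     "group1": {"s01": {"Age": 24, "Eyesight": "normal"}, ...},
#'     "group2": {...}
#'   },
#'   "Stimuli": {"type_A": ["stimA1", ...], "type_B": [...]},
#'   "Control": ["stimA1"],
#'   "Analysis_Params": {
#'     "screen_width": 1280, "screen_height": 1024,
#'     "sampling_freq": 1000, "store_mode": "csv"
#'   }
#' }
#' ```
#'
#' Subject names must be unique across groups, control stimuli must exist
#' among the stimuli, and `Analysis_Params.sampling_freq` is required.
#' Unknown top-level keys warn but do not fail.
#'
#' @param path JSON file path.
#' @return A list with class `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  key <- function(obj, name) {
    hit <- which(tolower(names(obj)) == tolower(name))
    if (length(hit) == 0) NULL else obj[[hit[1]]]
  }
  known <- c("Experiment_name", "Subjects", "Stimuli", "Control", "Analysis_Params")
  unknown <- names(raw)[!tolower(names(raw)) %in% tolower(known)]
  if (length(unknown) > 0) {
    rlang::warn(paste0("ignoring unknown config key(s): ",
                       paste(unknown, collapse = ", ")))
  }
  subjects <- key(raw, "Subjects")
  if (is.null(subjects) || length(subjects) == 0) {
    rlang::abort("config error at $.Subjects: at least one subject group required")
  }
  all_subjects <- unlist(purrr::map(subjects, names), use.names = FALSE)
  dup <- all_subjects[duplicated(all_subjects)]
  if (length(dup) > 0) {
    rlang::abort(paste0("config error at $.Subjects: subject(s) in more than one group: ",
                        paste(unique(dup), collapse = ", ")))
  }
  stimuli <- key(raw, "Stimuli")
  if (is.null(stimuli) || length(stimuli) == 0) {
    rlang::abort("config error at $.Stimuli: at least one stimulus group required")
  }
  all_stimuli <- unlist(stimuli, use.names = FALSE)
  control <- unlist(key(raw, "Control") %||% list(), use.names = FALSE)
  bad_ctrl <- setdiff(control, all_stimuli)
  if (length(bad_ctrl) > 0) {
    rlang::abort(paste0("config error at $.Control: unknown stimulus: ",
                        paste(bad_ctrl, collapse = ", ")))
  }
  ap <- key(raw, "Analysis_Params")
  if (is.null(ap)) rlang::abort("config error at $.Analysis_Params: missing")
  sfreq <- key(ap, "sampling_freq")
  if (is.null(sfreq)) {
    rlang::abort("config error at $.Analysis_Params.sampling_freq: missing")
  }
  structure(
    list(
      name = key(raw, "Experiment_name") %||% "experiment",
      subjects = subjects,
      stimuli = stimuli,
      control = as.character(control),
      screen_width = key(ap, "screen_width") %||% 1280,
      screen_height = key(ap, "screen_height") %||% 1024,
      sampling_freq = as.numeric(sfreq),
      store_mode = key(ap, "store_mode") %||% "csv",
      detection = key(ap, "detection") %||% list()
    ),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>", x$name, "\n")
  cat("  subjects:", length(unlist(purrr::map(x$subjects, names))),
      "in", length(x$subjects), "group(s)\n")
  cat("  stimuli:", length(unlist(x$stimuli)), "in", length(x$stimuli),
      "group(s);", length(x$control), "control(s)\n")
  cat("  screen:", x$screen_width, "x", x$screen_height, "px at",
      x$sampling_freq, "Hz\n")
  invisible(x)
}

config_subject_table <- function(config) {
  rows <- purrr::imap(config$subjects, function(members, grp) {
    tibble(
      subject = names(members),
      subject_group = grp,
      age = purrr::map_dbl(members, ~ as.numeric(.x$Age %||% NA_real_)),
      eyesight = purrr::map_chr(members, ~ as.character(.x$Eyesight %||% NA_character_))
    )
  })
  dplyr::bind_rows(rows)
}

config_stimulus_table <- function(config) {
  dplyr::bind_rows(purrr::imap(config$stimuli, function(members, grp) {
    tibble(stimulus = unlist(members), stimulus_group = grp)
  }))
}

config_detection <- function(config) {
  do.call(detection_config, config$detection)
}

#' Run a whole experiment from its config
#'
#' Executes the requested pipeline stages over every
#' (subject, stimulus) trial named in the config and writes a
#' deterministic artifact tree under `out_dir`:
#'
#' * `extract` — 21-parameter extraction per trial ->
#'   `parameters.csv`
#' * `normalize` — control-stimulus normalization (requires controls in
#'   the config) -> `parameters_normalized.csv`
#' * `analyze` — the statistical test described by `test_spec`
#'   (`list(test=, between=, within=, parameters=)`) ->
#'   `test_<name>.csv`
#' * `visualize` — fixation plot and gaze heat map per trial under
#'   `plots/`
#'
#' A `run_log.txt` with the config hash is always written. Removing a
#' subject or stimulus from the JSON removes it from every output.
#'
#' @param config An `experiment_config` or path to one.
#' @param data_dir Folder of base-format CSVs (defaults to `base/` next
#'   to the config when `config` is a path).
#' @param out_dir Artifact folder.
#' @param actions Subset of `c("extract", "normalize", "analyze",
#'   "visualize")`.
#' @param test_spec List describing the test for `analyze`.
#' @param aoi Optional `aoi_spec` (or named per-stimulus list) used
#'   during extraction.
#' @return Tibble of extracted parameters, invisibly.
#' @export
run_experiment <- function(config, data_dir = NULL, out_dir = "results",
                           actions = c("extract", "analyze"),
                           test_spec = list(test = "mixed_anova",
                                            between = "subject_group",
                                            within = "stimulus_group",
                                            parameters = "all"),
                           aoi = NULL) {
  if (is.character(config)) {
    data_dir <- data_dir %||% file.path(dirname(config), "base")
    config <- load_config(config)
  }
  if (is.null(data_dir)) rlang::abort("`data_dir` required when config is an object")
  bad <- setdiff(actions, c("extract", "normalize", "analyze", "visualize"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown action(s): ", paste(bad, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  subjects <- unlist(purrr::map(config$subjects, names), use.names = FALSE)
  stimuli <- unlist(config$stimuli, use.names = FALSE)
  wanted <- tidyr::expand_grid(subject = sort(subjects), stimulus = sort(stimuli))
  files <- file.path(data_dir, paste0(wanted$subject, "__", wanted$stimulus, ".csv"))
  absent <- !file.exists(files)
  if (any(absent)) {
    rlang::abort(paste0(
      "missing trial file(s) for: ",
      paste(paste0("(", wanted$subject[absent], ", ", wanted$stimulus[absent], ")"),
            collapse = ", ")
    ))
  }
  cfg <- config_detection(config)
  writeLines(
    c(paste0("experiment: ", config$name),
      paste0("config_hash: ", rlang::hash(config)),
      paste0("n_trials: ", nrow(wanted)),
      paste0("actions: ", paste(actions, collapse = ","))),
    file.path(out_dir, "run_log.txt")
  )

  sets <- purrr::map_dfr(seq_len(nrow(wanted)), function(i) {
    trial <- read_base_csv(files[i])
    this_aoi <- if (inherits(aoi, "aoi_spec")) aoi else aoi[[wanted$stimulus[i]]]
    suppressWarnings(extract_parameter_set(trial, cfg, this_aoi))
  })

  if ("extract" %in% actions) {
    export_parameters_csv(sets, file.path(out_dir, "parameters.csv"))
  }
  analysis_sets <- sets
  if ("normalize" %in% actions) {
    if (length(config$control) == 0) {
      rlang::abort("normalize requested but the config lists no control stimuli")
    }
    analysis_sets <- normalize_with_controls(sets, config$control)
    export_parameters_csv(analysis_sets,
                          file.path(out_dir, "parameters_normalized.csv"))
  }
  if ("analyze" %in% actions) {
    long <- build_long_table(analysis_sets, config,
                             parameters = test_spec$parameters %||% "all")
    fit <- run_statistical_test(
      long, test = test_spec$test,
      between = test_spec$between %||% character(),
      within = test_spec$within %||% character(),
      out_csv = file.path(out_dir, paste0("test_", test_spec$test, ".csv"))
    )
  }
  if ("visualize" %in% actions) {
    plot_dir <- file.path(out_dir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(wanted))) {
      trial <- read_base_csv(files[i])
      stem <- paste0(wanted$subject[i], "__", wanted$stimulus[i])
      events <- suppressWarnings(detect_events(trial, cfg))
      render_plot(
        "fixation_plot",
        list(fixations = events[events$kind == "fixation", ]),
        out_path = file.path(plot_dir, paste0(stem, "_fixations.png")),
        screen = c(config$screen_height, config$screen_width)
      )
      render_plot(
        "heatmap", list(gaze = gaze_trace(trial)),
        out_path = file.path(plot_dir, paste0(stem, "_heatmap.png")),
        screen = c(config$screen_height, config$screen_width)
      )
    }
  }
  invisible(sets)
}
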