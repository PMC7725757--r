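#' Build the long-format parameter table
#'
#' Pivots per-trial parameter sets into one row per
#' (subject, stimulus, parameter) and attaches the experiment config's
#' factor structure: subject group, stimulus group, and any per-subject
#' attributes (Age, Eyesight, ...) as candidate between factors.
#'
#' @param sets Parameter-set tibble (rows from [extract_parameter_set()]).
#' @param config Experiment config from [load_config()].
#' @param parameters Parameter names to keep, or `"all"`.
#' @return Long tibble with columns `subject`, `subject_group`,
#'   `stimulus`, `stimulus_group`, one column per subject attribute,
#'   `parameter`, `value`.
#' @export
build_long_table <- function(sets, config, parameters = "all") {
  if (identical(parameters, "all")) {
    parameters <- eye_parameter_names()
  } else {
    bad <- setdiff(parameters, eye_parameter_names())
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "unknown parameter(s): ", paste(bad, collapse = ", "),
        "; valid names are: ", paste(eye_parameter_names(), collapse = ", ")
      ))
    }
  }
  subj_map <- config_subject_table(config)
  stim_map <- config_stimulus_table(config)
  long <- sets |>
    tidyr::pivot_longer(dplyr::all_of(intersect(eye_parameter_names(), names(sets))),
                        names_to = "parameter", values_to = "value") |>
    dplyr::filter(.data$parameter %in% parameters) |>
    dplyr::rename(subject = "subject_id", stimulus = "stimulus_name") |>
    dplyr::left_join(subj_map, by = "subject") |>
    dplyr::left_join(stim_map, by = "stimulus")
  attr_cols <- setdiff(names(subj_map), c("subject", "subject_group"))
  long[, c("subject", "subject_group", "stimulus", "stimulus_group",
           attr_cols, "parameter", "value")]
}

#' Run a statistical test over every parameter
#'
#' The test matrix mirrors common group-comparison practice in
#' eye-movement research:
#'
#' * `mixed_anova` — one between factor and one within factor, subjects
#'   nested in the between factor (`aov` with an `Error(subject/within)`
#'   stratum). Values are averaged over replicate trials within each
#'   (subject, within-level) cell first.
#' * `rm_anova` — repeated-measures ANOVA with one or two within factors.
#' * `nway_anova` — factorial between-subjects ANOVA with any number of
#'   between factors.
#' * `pairwise_t` — paired Student's t tests across all level pairs of
#'   one within factor.
#' * `welch_t` — Welch's unequal-variance t test on exactly one factor
#'   (pairwise across its level pairs if there are more than two).
#'
#' Parameters whose cells have zero variance are skipped with a warning.
#' No multiple-testing correction is applied across parameters by
#' default; set `p_adjust` to a [stats::p.adjust()] method to add one.
#'
#' @param table Long table from [build_long_table()] (or
#'   [simulate_null_long_table()]).
#' @param test One of `"mixed_anova"`, `"rm_anova"`, `"nway_anova"`,
#'   `"pairwise_t"`, `"welch_t"`.
#' @param between,within Factor column names.
#' @param p_adjust `"none"` (default) or a `p.adjust` method applied per
#'   effect across parameters.
#' @param out_csv Optional path; the tidy results are also written there.
#' @return An object of class `gaze_test`; its `tidy()` method (also the
#'   `$results` element) is a tibble with columns `parameter`, `effect`,
#'   `df1`, `df2`, `statistic`, `p_value`.
#' @export
run_statistical_test <- function(table,
                                 test = c("mixed_anova", "rm_anova",
                                          "nway_anova", "pairwise_t", "welch_t"),
                                 between = character(),
                                 within = character(),
                                 p_adjust = "none",
                                 out_csv = NULL) {
  test <- match.arg(test)
  check_arity(test, between, within)
  for (f in c(between, within)) {
    if (!f %in% names(table)) rlang::abort(paste0("factor column not found: ", f))
  }
  params <- unique(table$parameter)
  results <- purrr::map(params, function(pm) {
    dat <- table[table$parameter == pm, , drop = FALSE]
    dat <- dat[!is.na(dat$value), , drop = FALSE]
    cells <- interaction(dat[, c(between, within), drop = FALSE], drop = TRUE)
    if (stats::var(dat$value) == 0 ||
        all(tapply(dat$value, cells, function(v) length(unique(v))) == 1)) {
      rlang::warn(paste0("zero-variance cells for parameter '", pm, "'; test skipped"))
      return(NULL)
    }
    res <- switch(test,
      mixed_anova = fit_mixed_anova(dat, between, within),
      rm_anova = fit_rm_anova(dat, within),
      nway_anova = fit_nway_anova(dat, between),
      pairwise_t = fit_pairwise_t(dat, within, paired = TRUE),
      welch_t = fit_welch_t(dat, c(between, within))
    )
    res$parameter <- pm
    res
  })
  results <- dplyr::bind_rows(results)
  if (nrow(results) > 0) {
    results <- results[, c("parameter", "effect", "df1", "df2", "statistic", "p_value")]
    if (!identical(p_adjust, "none")) {
      results <- results |>
        dplyr::group_by(.data$effect) |>
        dplyr::mutate(p_value = stats::p.adjust(.data$p_value, method = p_adjust)) |>
        dplyr::ungroup()
    }
  }
  if (!is.null(out_csv)) readr::write_csv(results, out_csv)
  structure(
    list(results = results, test = test, between = between, within = within),
    class = "gaze_test"
  )
}

check_arity <- function(test, between, within) {
  msg <- switch(test,
    mixed_anova = if (length(between) != 1 || length(within) != 1) {
      "mixed_anova requires exactly one between and one within factor"
    },
    rm_anova = if (length(within) < 1 || length(within) > 2 || length(between) > 0) {
      "rm_anova requires one or two within factors and no between factor"
    },
    nway_anova = if (length(between) < 1 || length(within) > 0) {
      "nway_anova requires at least one between factor and no within factor"
    },
    pairwise_t = if (length(within) != 1 || length(between) > 0) {
      "pairwise_t requires exactly one within factor"
    },
    welch_t = if (length(between) + length(within) != 1) {
      "welch_t requires exactly one factor (between or within)"
    }
  )
  if (!is.null(msg)) rlang::abort(msg, class = "gazemetrics_arity_error")
}

# average replicate trials within each (subject x within-cell) before a
# repeated-measures fit, so the Error stratum is balanced
collapse_cells <- function(dat, between, within) {
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", between, within)))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

anova_error_tidy <- function(fit) {
  tabs <- summary(fit)
  out <- list()
  for (stratum in tabs) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    effects <- trimws(rownames(tab))
    resid_row <- which(effects == "Residuals")
    if (length(resid_row) == 0) next
    df2 <- tab$Df[resid_row]
    for (r in seq_len(nrow(tab))) {
      if (r == resid_row) next
      out[[length(out) + 1]] <- tibble(
        effect = effects[r], df1 = tab$Df[r], df2 = df2,
        statistic = tab$`F value`[r], p_value = tab$`Pr(>F)`[r]
      )
    }
  }
  dplyr::bind_rows(out)
}

fit_mixed_anova <- function(dat, between, within) {
  dat <- collapse_cells(dat, between, within)
  dat$..b <- factor(dat[[between]])
  dat$..w <- factor(dat[[within]])
  dat$subject <- factor(dat$subject)
  fit <- stats::aov(value ~ ..b * ..w + Error(subject / ..w), data = dat)
  tidy_tab <- anova_error_tidy(fit)
  tidy_tab$effect <- stringr::str_replace_all(
    tidy_tab$effect, c("\\.\\.b" = between, "\\.\\.w" = within)
  )
  tidy_tab
}

fit_rm_anova <- function(dat, within) {
  dat <- collapse_cells(dat, character(), within)
  dat$subject <- factor(dat$subject)
  for (i in seq_along(within)) dat[[paste0("..w", i)]] <- factor(dat[[within[i]]])
  wvars <- paste0("..w", seq_along(within))
  rhs <- paste(wvars, collapse = " * ")
  form <- stats::as.formula(paste0("value ~ ", rhs,
                                   " + Error(subject / (", rhs, "))"))
  fit <- stats::aov(form, data = dat)
  tidy_tab <- anova_error_tidy(fit)
  repl <- stats::setNames(within, paste0("\\.\\.w", seq_along(within)))
  tidy_tab$effect <- stringr::str_replace_all(tidy_tab$effect, repl)
  tidy_tab
}

fit_nway_anova <- function(dat, between) {
  dat <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", between)))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  for (f in between) dat[[f]] <- factor(dat[[f]])
  form <- stats::as.formula(paste0("value ~ ", paste(between, collapse = " * ")))
  fit <- stats::aov(form, data = dat)
  tab <- as.data.frame(summary(fit)[[1]])
  effects <- trimws(rownames(tab))
  resid_row <- which(effects == "Residuals")
  tibble(
    effect = effects[-resid_row], df1 = tab$Df[-resid_row],
    df2 = tab$Df[resid_row], statistic = tab$`F value`[-resid_row],
    p_value = tab$`Pr(>F)`[-resid_row]
  )
}

fit_pairwise_t <- function(dat, within, paired = TRUE) {
  dat <- collapse_cells(dat, character(), within)
  levels <- sort(unique(dat[[within[1]]]))
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- dat[dat[[within[1]]] == pr[1], c("subject", "value")]
    b <- dat[dat[[within[1]]] == pr[2], c("subject", "value")]
    common <- intersect(a$subject, b$subject)
    tt <- stats::t.test(a$value[match(common, a$subject)],
                        b$value[match(common, b$subject)],
                        paired = TRUE)
    tibble(
      effect = paste0(within[1], ": ", pr[1], " vs ", pr[2]),
      df1 = 1, df2 = unname(tt$parameter),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
}

fit_welch_t <- function(dat, factor_name) {
  f <- factor_name[1]
  agg <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", f)))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  levels <- sort(unique(agg[[f]]))
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- agg$value[agg[[f]] == pr[1]]
    b <- agg$value[agg[[f]] == pr[2]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble(
      effect = paste0(f, ": ", pr[1], " vs ", pr[2]),
      df1 = 1, df2 = unname(tt$parameter),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
}

#' @export
print.gaze_test <- function(x, ...) {
  cat("<gaze_test>", x$test, "\n")
  if (length(x$between)) cat("  between:", paste(x$between, collapse = ", "), "\n")
  if (length(x$within)) cat("  within:", paste(x$within, collapse = ", "), "\n")
  print(x$results, n = 20)
  invisible(x)
}

#' Tidy / summarise a statistical-test result
#'
#' `tidy()` returns the per-effect results table; `glance()` a one-row
#' summary with the number of parameters tested and of effects
#' significant at `alpha`.
#'
#' @param x A `gaze_test` object.
#' @param alpha Significance level used by `glance()`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gaze_test
#' @export
tidy.gaze_test <- function(x, ...) x$results

#' @rdname tidy.gaze_test
#' @method glance gaze_test
#' @export
glance.gaze_test <- function(x, alpha = 0.05, ...) {
  tibble(
    test = x$test,
    n_parameters = length(unique(x$results$parameter)),
    n_effects = nrow(x$results),
    n_significant = sum(x$results$p_value < alpha, na.rm = TRUE),
    alpha = alpha
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Export extracted parameters to CSV
#'
#' One row per (subject, stimulus) with the 21 parameter columns; the
#' header is the frozen serialization order. An empty input writes a
#' header-only file with a warning.
#'
#' @param sets Parameter-set tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameters_csv <- function(sets, path) {
  cols <- c("subject_id", "stimulus_name", eye_parameter_names())
  if (nrow(sets) == 0) {
    rlang::warn("no parameter sets; writing header-only CSV")
    sets <- as_tibble(stats::setNames(
      as.list(rep(list(numeric(0)), length(cols))), cols
    ))
    sets$subject_id <- character(0)
    sets$stimulus_name <- character(0)
  }
  readr::write_csv(sets[, cols], path)
  invisible(path)
}
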