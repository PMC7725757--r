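# one shared synthetic experiment for the whole file (extraction over the
# 6 x 6 grid is the expensive step)
xp <- local({
  dir <- tempfile("stats-exp")
  cfg <- make_synthetic_experiment(
    dir,
    n_subjects_per_group = 3,
    stimuli_per_group = list(type_A = paste0("stimA", 1:3),
                             type_B = paste0("stimB", 1:3)),
    seed = 6
  )
  files <- list.files(file.path(dir, "base"), full.names = TRUE)
  sets <- purrr::map_dfr(files, function(f) {
    suppressWarnings(extract_parameter_set(read_base_csv(f)))
  })
  unlink(dir, recursive = TRUE)
  list(cfg = cfg, sets = sets)
})

test_that("the long table has one row per subject x stimulus x parameter", {
  long <- build_long_table(xp$sets, xp$cfg)
  expect_equal(nrow(long), 6 * 6 * 21)
  long1 <- build_long_table(xp$sets, xp$cfg, parameters = "saccade_count")
  expect_equal(nrow(long1), 36)
  expect_setequal(unique(long$subject_group), c("group1", "group2"))
  expect_setequal(unique(long$stimulus_group), c("type_A", "type_B"))
  expect_true(all(c("age", "eyesight") %in% names(long)))
  expect_error(build_long_table(xp$sets, xp$cfg, parameters = "nonsense"),
               "valid names")
})

test_that("welch_t reproduces the hand-computed statistic", {
  tab <- tibble::tibble(
    subject = paste0("s", 1:6),
    subject_group = rep(c("g1", "g2"), each = 3),
    stimulus = "x", stimulus_group = "w",
    parameter = "pupil_mean", value = c(1, 2, 3, 4, 5, 6)
  )
  fit <- run_statistical_test(tab, "welch_t", between = "subject_group")
  res <- tidy(fit)
  # t = (2 - 5) / sqrt(1/3 + 1/3), Welch df = 4 for equal n and variance
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df2, 4, tolerance = 1e-6)
  g <- glance(fit)
  expect_equal(g$n_parameters, 1)
})

test_that("identical groups give a null statistic", {
  tab <- tibble::tibble(
    subject = paste0("s", 1:8),
    subject_group = rep(c("g1", "g2"), each = 4),
    stimulus = "x", stimulus_group = "w",
    parameter = "p", value = rep(c(1, 2, 3, 4), 2)
  )
  res <- tidy(run_statistical_test(tab, "welch_t", between = "subject_group"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("arity limits are policed for every test", {
  tab <- simulate_null_long_table(seed = 1)
  expect_error(run_statistical_test(tab, "mixed_anova", between = "subject_group"),
               class = "gazemetrics_arity_error")
  expect_error(run_statistical_test(tab, "rm_anova",
                                    within = c("a", "b", "c")),
               class = "gazemetrics_arity_error")
  expect_error(run_statistical_test(tab, "welch_t",
                                    between = "subject_group",
                                    within = "stimulus_group"),
               class = "gazemetrics_arity_error")
  expect_error(run_statistical_test(tab, "nway_anova",
                                    within = "stimulus_group"),
               class = "gazemetrics_arity_error")
})

test_that("zero-variance parameters are skipped with a warning", {
  tab <- simulate_null_long_table(seed = 2)
  tab$value <- 1
  expect_warning(fit <- run_statistical_test(tab, "welch_t",
                                             between = "subject_group"),
                 "zero-variance")
  expect_equal(nrow(tidy(fit)), 0)
})

test_that("an injected 3-SD group effect is detected reliably by mixed ANOVA", {
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    tab <- simulate_null_long_table(n_per_group = 6, n_within = 2,
                                    seed = 3000 + r)
    tab$value[tab$subject_group == "group2"] <-
      tab$value[tab$subject_group == "group2"] + 3
    fit <- run_statistical_test(tab, "mixed_anova",
                                between = "subject_group",
                                within = "stimulus_group")
    p <- tidy(fit)$p_value[tidy(fit)$effect == "subject_group"]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("rm_anova handles two within factors and reports both effects", {
  a <- simulate_null_long_table(n_per_group = 4, n_within = 2, seed = 9)
  b <- simulate_null_long_table(n_per_group = 4, n_within = 2, seed = 10)
  a$brightness <- "low"
  b$brightness <- "high"
  tab <- dplyr::bind_rows(a, b)
  fit <- run_statistical_test(tab, "rm_anova",
                              within = c("stimulus_group", "brightness"))
  effects <- tidy(fit)$effect
  expect_true("stimulus_group" %in% effects)
  expect_true("brightness" %in% effects)
  expect_true("stimulus_group:brightness" %in% effects)
})

test_that("pairwise_t runs paired tests across within-level pairs", {
  tab <- simulate_null_long_table(n_per_group = 5, n_within = 3, seed = 12)
  fit <- run_statistical_test(tab, "pairwise_t", within = "stimulus_group")
  expect_equal(nrow(tidy(fit)), choose(3, 2))
  expect_equal(unique(tidy(fit)$df2), 9) # 10 subjects paired: df = n - 1
})

test_that("parameter CSV export round-trips and handles empty input", {
  path <- withr::local_tempfile(fileext = ".csv")
  export_parameters_csv(xp$sets, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 36)
  expect_identical(names(back), c("subject_id", "stimulus_name",
                                  eye_parameter_names()))
  expect_equal(back$pupil_mean, xp$sets$pupil_mean)
  empty_path <- withr::local_tempfile(fileext = ".csv")
  expect_warning(export_parameters_csv(xp$sets[0, ], empty_path), "header-only")
  expect_equal(nrow(readr::read_csv(empty_path, show_col_types = FALSE)), 0)
})
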