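test_that("the night task restricts to the PSG window with PSG truth", {
  n <- 1500L
  stage <- rep(NA_integer_, n)
  stage[(100:1300) + 1L] <- rep(c(0L, 2L), length.out = 1201L)
  s <- epoch_series("A", rep(10, n), psg_stage = stage,
                    annotation = rep(1L, n))
  e <- build_task_night(s)
  expect_length(e$truth, 1201L)
  expect_equal(e$truth, stages_to_hypnogram(stage[(100:1300) + 1L]))
  expect_true(all(e$provenance == "psg"))

  all_wake <- epoch_series("B", rep(1, 20),
                           psg_stage = c(NA, rep(0L, 18), NA))
  expect_true(all(build_task_night(all_wake)$truth == 0L))
  expect_error(build_task_night(epoch_series("C", 1:5)),
               class = "actisleep_validation_error")
})

test_that("the night-and-day task pads with annotation truth and never overrides PSG", {
  cfg <- simulation_config(n_subjects = 3, seed = 21,
                           annotation_flip_prob = 0.1)
  cohort <- generate_cohort(cfg)
  for (s in cohort) {
    e <- build_task_nightday(s, pad_hours = 8)
    expect_false(anyNA(e$truth))
    inside <- e$provenance == "psg"
    idx <- (e$range[1]:e$range[2]) + 1L
    expect_equal(e$truth[inside],
                 stages_to_hypnogram(s$psg_stage[idx][inside]))
    expect_equal(e$truth[!inside], s$annotation[idx][!inside])
    # pad is limited by available data
    expect_gte(e$range[1], 0)
    expect_lte(e$range[2], length(s) - 1L)
  }
  # degenerate pad equals the night task
  s <- cohort[[1]]
  e0 <- build_task_nightday(s, pad_hours = 0)
  en <- build_task_night(s)
  expect_equal(e0$truth, en$truth)
  expect_equal(e0$counts, en$counts)
})

test_that("day naps are labeled sleep in the night-and-day truth", {
  cfg <- simulation_config(n_subjects = 1, seed = 33,
                           annotation_flip_prob = 0,
                           day_sleep_fraction = 0.3)
  s <- generate_subject(cfg, 1)
  e <- build_task_nightday(s)
  idx <- (e$range[1]:e$range[2]) + 1L
  day_nap <- !is.na(e$provenance) & e$provenance == "annotation" &
    s$hidden_state[idx] == 1L
  expect_gt(sum(day_nap), 0)
  expect_true(all(e$truth[day_nap] == 1L))
})

test_that("a data-limited leading pad is truncated to the available epochs", {
  n <- 1400L
  stage <- rep(NA_integer_, n)
  stage[(240:1340) + 1L] <- 1L  # PSG starts 2 h into the record
  s <- epoch_series("lim", rep(5, n), psg_stage = stage,
                    annotation = rep(0L, n))
  e <- build_task_nightday(s, pad_hours = 8)
  expect_equal(unname(e$range[1]), 0L)  # only 2 h available before PSG
  expect_equal(unname(e$range[2]), min(n - 1L, 1340L + 960L))
})

test_that("baselines behave as defined", {
  s <- toy_series()
  e <- build_task_night(s)
  expect_true(all(make_baseline("always_sleep")(e) == 1L))
  expect_true(all(make_baseline("always_wake")(e) == 0L))
  expect_identical(make_baseline("device")(e),
                   score("oakley", e$counts,
                         overrides = list(theta = 40))$predictions)
  expect_identical(make_baseline("manual")(e), e$annotation)
  expect_error(make_baseline("oracle2"), class = "actisleep_config_error")
  m_sleep <- epoch_metrics(make_baseline("always_sleep")(e), e$truth)
  expect_equal(m_sleep$sensitivity, 100)
  expect_equal(m_sleep$specificity, 0)
  m_wake <- epoch_metrics(make_baseline("always_wake")(e), e$truth)
  expect_equal(m_wake$specificity, 100)
})

test_that("the benchmark harness reports oracle, baselines and rescored variants", {
  cfg <- simulation_config(n_subjects = 5, seed = 17)
  cohort <- generate_cohort(cfg)
  night <- build_task(cohort, "night")
  bm <- run_benchmark(night, methods = c("cole_kripke", "sadeh"),
                      rescore = TRUE)
  # 1 oracle + 4 baselines + 2 methods * (1 + rescore)
  expect_equal(nrow(bm$summary), 1L + 4L + 2L * 2L)

  oracle <- bm$summary[bm$summary$method == "Ground truth", ]
  expect_equal(oracle$accuracy_mean, 100)
  expect_equal(oracle$mae_waso, 0)
  expect_equal(oracle$mae_sleep_eff, 0)

  # always-sleep accuracy equals the mean per-subject sleep fraction
  sleep_frac <- vapply(night, function(e) mean(e$truth == 1L), numeric(1))
  as_row <- bm$summary[bm$summary$method == "Always sleep", ]
  expect_equal(as_row$accuracy_mean, 100 * mean(sleep_frac),
               tolerance = 1e-10)
  expect_equal(as_row$waso_mean, 0)
  expect_equal(as_row$sleep_eff_mean, 100)

  # rescoring is anti-monotone in sensitivity, per subject
  for (nm in c("cole_kripke", "sadeh")) {
    raw <- bm$per_subject[[nm]]$sensitivity
    resc <- bm$per_subject[[paste("Resc.", nm)]]$sensitivity
    expect_true(all(resc <= raw + 1e-9))
  }

  # the device baseline row equals an explicit oakley theta=40 method row
  bm2 <- run_benchmark(night, methods = list(
    oakley40 = function(e) score("oakley", e$counts,
                                 overrides = list(theta = 40))$predictions))
  dev <- bm2$summary[bm2$summary$method == "Device algorithm",
                     !(names(bm2$summary) %in% c("method", "group"))]
  oak <- bm2$summary[bm2$summary$method == "oakley40",
                     !(names(bm2$summary) %in% c("method", "group"))]
  expect_equal(unname(unlist(dev)), unname(unlist(oak)), tolerance = 1e-12)

  # significance matrices cover every method x baseline pair with valid p
  expect_true(all(bm$significance$accuracy >= 0 & bm$significance$accuracy <= 1))
  expect_equal(dim(bm$significance$f1), c(4L, 4L))
})

test_that("the night-and-day benchmark omits the oracle and clinical-error columns", {
  cfg <- simulation_config(n_subjects = 4, seed = 19)
  cohort <- generate_cohort(cfg)
  nd <- build_task(cohort, "night_day")
  bm <- run_benchmark(nd, methods = c("sazonov"))
  expect_false("Ground truth" %in% bm$summary$method)
  expect_false("mae_waso" %in% names(bm$summary))
  expect_equal(nrow(bm$summary), 5L)
})

test_that("benchmark reports serialize to delimited text and JSON", {
  cfg <- simulation_config(n_subjects = 3, seed = 23)
  night <- build_task(generate_cohort(cfg), "night")
  bm <- run_benchmark(night, methods = c("webster"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_benchmark_report(bm, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), nrow(bm$summary))
  rep_ <- jsonlite::read_json(js)
  expect_equal(rep_$manifest$task, "night")
})
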