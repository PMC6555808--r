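test_that("stage collapse maps all sleep stages to 1 and preserves missingness", {
  expect_equal(stages_to_hypnogram(c(0L, 0L, 0L)), c(0L, 0L, 0L))
  expect_equal(stages_to_hypnogram(1:5), rep(1L, 5))
  expect_equal(stages_to_hypnogram(c(0L, NA, 2L)), c(0L, NA, 1L))
  expect_error(stages_to_hypnogram(c(0L, 7L)),
               class = "actisleep_validation_error")
  set.seed(5)
  for (i in 1:20) {
    st <- sample(c(0:5, NA), 40, replace = TRUE)
    h <- stages_to_hypnogram(st)
    expect_length(h, 40)
    expect_identical(is.na(h), is.na(st))
  }
})

test_that("epoch series validates its channels and infers the PSG window", {
  expect_error(epoch_series("a", c(3, -1, 2)),
               class = "actisleep_validation_error")
  expect_error(epoch_series("a", numeric(0)),
               class = "actisleep_validation_error")
  expect_error(epoch_series("a", 1:3, epoch_length_s = 0),
               class = "actisleep_validation_error")
  s <- epoch_series("a", c(1, 2, 3, 4), psg_stage = c(0L, 2L, 5L, NA))
  expect_equal(unname(s$psg_window), c(0L, 2L))
})

test_that("native epoch tables roundtrip exactly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:80, 1)
    counts <- round(stats::rexp(n, 1 / 60), 3)
    counts[stats::runif(n) < 0.1] <- NA
    psg <- sort(sample(0:(n - 1), 2))
    stage <- rep(NA_integer_, n)
    stage[(psg[1]:psg[2]) + 1] <- sample(0:5, diff(psg) + 1, replace = TRUE)
    ann <- sample(c(0L, 1L, NA), n, replace = TRUE)
    st <- if (i %% 2 == 0)
      as.POSIXct("2001-05-04 21:00:00", tz = "UTC") else NULL
    orig <- epoch_series(paste0("S", i), counts, psg_stage = stage,
                         annotation = ann, start_time = st)
    write_epoch_table(orig, tmp)
    back <- read_epoch_table(tmp)[[orig$subject_id]]
    expect_equal(back$counts, orig$counts)
    expect_equal(back$psg_stage, orig$psg_stage)
    expect_equal(back$annotation, orig$annotation)
    expect_equal(back$psg_window, orig$psg_window)
    expect_equal(back$subject_id, orig$subject_id)
    if (!is.null(st)) expect_equal(back$start_time, orig$start_time)
  }
})

test_that("a toy table yields the expected stages and PSG window", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,epoch_idx,timestamp,activity,stage,annotation",
               "X,0,,12,0,",
               "X,1,,0,2,",
               "X,2,,3,5,",
               "X,3,,40,,"), tmp)
  s <- read_epoch_table(tmp)[["X"]]
  expect_equal(s$psg_stage, c(0L, 2L, 5L, NA))
  expect_equal(stages_to_hypnogram(s), c(0L, 1L, 1L, NA))
  expect_equal(unname(s$psg_window), c(0L, 2L))
})

test_that("table reading rejects bad input and unknown dialects", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,epoch_idx,timestamp,activity",
               "X,0,,5", "X,1,,-1"), tmp)
  expect_error(read_epoch_table(tmp), class = "actisleep_validation_error")
  writeLines(c("subject_id,epoch_idx,timestamp,activity",
               "X,0,,5", "X,0,,3"), tmp)
  expect_error(read_epoch_table(tmp), "duplicated epoch index",
               class = "actisleep_validation_error")
  expect_error(read_epoch_table(tmp, dialect = "nope"),
               class = "actisleep_config_error")
})

test_that("the MESA dialect maps rest intervals onto the annotation channel", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mesaid,linetime,activity,stage,interval,wake",
               "345,21:00:00,88,,ACTIVE,1",
               "345,21:00:30,0,0,REST,0",
               "345,21:01:00,2,2,REST-S,0",
               "345,21:01:30,1,5,EXCLUDED,0"), tmp)
  s <- read_epoch_table(tmp, dialect = "mesa")[["345"]]
  expect_equal(s$annotation, c(0L, 1L, 1L, NA))
  expect_equal(s$psg_stage, c(NA, 0L, 2L, 5L))
  expect_equal(unname(s$psg_window), c(1L, 3L))
})

test_that("cohort filters apply the overlap, 3-h and 16-h rules", {
  per_h <- 120L  # 30-s epochs
  mk <- function(id, usable_h, psg_h) {
    n <- as.integer(psg_h * per_h) + 20L
    stage <- c(rep(NA_integer_, 10L),
               rep(0L, as.integer(psg_h * per_h)),
               rep(NA_integer_, 10L))
    counts <- rep(NA_real_, n)
    counts[10L + seq_len(as.integer(usable_h * per_h))] <- 5
    epoch_series(id, counts, psg_stage = stage)
  }
  short <- mk("short", usable_h = 2, psg_h = 10)
  long_psg <- mk("long", usable_h = 17, psg_h = 17)
  good <- mk("good", usable_h = 10, psg_h = 10)
  none <- epoch_series("none", rep(1, 50))

  res <- apply_cohort_filters(list(short, long_psg, good, none))
  expect_equal(names(res$kept), "good")
  rep_ <- res$report
  expect_equal(rep_$rule[rep_$subject_id == "short"], "min_usable")
  expect_equal(rep_$rule[rep_$subject_id == "long"], "max_psg")
  expect_equal(rep_$rule[rep_$subject_id == "none"], "no_overlap")

  # idempotence and empty input
  twice <- apply_cohort_filters(res$kept)
  expect_equal(names(twice$kept), names(res$kept))
  expect_equal(nrow(twice$report), 0L)
  empty <- apply_cohort_filters(list())
  expect_length(empty$kept, 0L)
})

test_that("subject split reproduces the 80/20 cohort sizes and partitions", {
  sp <- split_subjects(sprintf("id%04d", 1:1817), 0.8, seed = 3)
  expect_length(sp$train_ids, 1454L)
  expect_length(sp$test_ids, 363L)

  sp10 <- split_subjects(letters[1:10], 0.8, seed = 1)
  expect_length(sp10$train_ids, 8L)

  expect_identical(split_subjects(letters[1:10], 0.8, seed = 9),
                   split_subjects(letters[1:10], 0.8, seed = 9))
  expect_error(split_subjects(c("a", "a", "b"), 0.5),
               class = "actisleep_validation_error")
  expect_error(split_subjects(letters[1:4], 1.0),
               class = "actisleep_validation_error")

  set.seed(2)
  for (i in 1:15) {
    ids <- sprintf("s%03d", sample(500, sample(3:60, 1)))
    fr <- stats::runif(1, 0.1, 0.9)
    sp <- split_subjects(ids, fr, seed = i)
    expect_setequal(c(sp$train_ids, sp$test_ids), ids)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    expect_length(sp$train_ids, floor(length(ids) * fr + 0.5))
  }
})
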