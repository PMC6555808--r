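# Evaluation tasks and the cohort benchmark harness.
#
# Task Night restricts evaluation to the PSG window, with the collapsed PSG
# hypnogram as truth. Task Night&Day extends the range up to a fixed number
# of hours on each side (data permitting); outside PSG the expert
# rest-interval annotation provides the truth, with annotated rest (naps
# included) scored as sleep. Annotation never overrides PSG where PSG
# exists.

.task_entry <- function(subject_id, task, range, counts, truth, annotation,
                        provenance, epoch_length_s) {
  structure(list(subject_id = subject_id, task = task, range = range,
                 counts = counts, truth = truth, annotation = annotation,
                 provenance = provenance, epoch_length_s = epoch_length_s),
            class = "task_entry")
}

#' Build the night evaluation task for one subject
#'
#' @param series An [epoch_series] with a PSG window.
#' @return A `task_entry` restricted to the PSG window, with truth from the
#'   collapsed PSG stages.
#' @export
build_task_night <- function(series) {
  if (!inherits(series, "epoch_series"))
    abort_validation("series must be an epoch_series")
  if (is.null(series$psg_window))
    abort_validation("subject '%s': no PSG window; night task undefined",
                     series$subject_id)
  idx <- (series$psg_window[1]:series$psg_window[2]) + 1L
  truth <- stages_to_hypnogram(series)[idx]
  ann <- if (is.null(series$annotation)) NULL else series$annotation[idx]
  .task_entry(series$subject_id, "night",
              range = series$psg_window,
              counts = series$counts[idx], truth = truth, annotation = ann,
              provenance = rep("psg", length(idx)),
              epoch_length_s = series$epoch_length_s)
}

#' Build the night-and-day evaluation task for one subject
#'
#' The evaluated range extends up to `pad_hours` before and after the PSG
#' window, truncated to the available data. Truth equals the PSG hypnogram
#' inside the window and the expert annotation outside it (annotated rest,
#' naps included, counts as sleep).
#'
#' @param series An [epoch_series] with PSG window and annotation channel.
#' @param pad_hours Maximum day-time extension on each side, in hours
#'   (default 8).
#' @return A `task_entry`.
#' @export
build_task_nightday <- function(series, pad_hours = 8) {
  if (!inherits(series, "epoch_series"))
    abort_validation("series must be an epoch_series")
  if (is.null(series$psg_window))
    abort_validation("subject '%s': no PSG window", series$subject_id)
  pad <- as.integer(floor(pad_hours * 3600 / series$epoch_length_s))
  first <- max(0L, series$psg_window[1] - pad)
  last <- min(length(series) - 1L, series$psg_window[2] + pad)
  idx <- (first:last) + 1L
  psg_part <- stages_to_hypnogram(series)[idx]
  inside <- idx - 1L >= series$psg_window[1] & idx - 1L <= series$psg_window[2]
  truth <- psg_part
  day_idx <- which(!inside)
  if (length(day_idx)) {
    if (is.null(series$annotation))
      abort_validation("subject '%s': no annotation channel for the day segment",
                       series$subject_id)
    ann <- series$annotation[idx]
    missing_day <- day_idx[is.na(ann[day_idx])]
    if (length(missing_day))
      abort_validation(
        "subject '%s': annotation missing on %d required day epoch(s), first at epoch %d",
        series$subject_id, length(missing_day),
        idx[missing_day[1]] - 1L)
    truth[!inside] <- ann[!inside]
  }
  ann_all <- if (is.null(series$annotation)) NULL else series$annotation[idx]
  .task_entry(series$subject_id, "night_day",
              range = c(first = first, last = last),
              counts = series$counts[idx], truth = truth,
              annotation = ann_all,
              provenance = ifelse(inside, "psg", "annotation"),
              epoch_length_s = series$epoch_length_s)
}

#' Build a task dataset over a cohort
#'
#' @param cohort List of [epoch_series].
#' @param task `"night"` or `"night_day"`.
#' @param pad_hours Padding for the night-and-day task.
#' @return List of `task_entry` objects with attribute `task`.
#' @export
build_task <- function(cohort, task = c("night", "night_day"),
                       pad_hours = 8) {
  task <- match.arg(task)
  entries <- lapply(cohort, function(s)
    if (task == "night") build_task_night(s)
    else build_task_nightday(s, pad_hours))
  structure(entries, task = task)
}

#' Baseline predictors
#'
#' @param name One of `"always_sleep"`, `"always_wake"`, `"device"` (the
#'   actigraphy device's native algorithm, i.e. the Oakley scorer at
#'   theta = 40) or `"manual"` (echoes the expert annotation channel).
#' @return A predictor: a function mapping a `task_entry` to a hypnogram.
#' @export
make_baseline <- function(name) {
  switch(name,
         always_sleep = function(entry) rep(1L, length(entry$counts)),
         always_wake = function(entry) rep(0L, length(entry$counts)),
         device = function(entry)
           score("oakley", entry$counts,
                 overrides = list(theta = 40))$predictions,
         manual = function(entry) {
           if (is.null(entry$annotation) || all(is.na(entry$annotation)))
             abort_validation("subject '%s': no annotation for manual baseline",
                              entry$subject_id)
           entry$annotation
         },
         abort_config("unknown baseline '%s'", name))
}

# Normalize a method spec to a predictor function. Character names refer to
# registered traditional scorers.
.as_predictor <- function(m) {
  if (is.function(m)) return(m)
  if (is.character(m) && length(m) == 1L) {
    nm <- m
    force(nm)
    return(function(entry) score(nm, entry$counts)$predictions)
  }
  abort_config("methods must be functions or registered scorer names")
}

.eval_method <- function(task_entries, predict_fn, is_night, rescored) {
  per <- lapply(task_entries, function(e) {
    pred <- as_hypnogram(predict_fn(e))
    if (length(pred) != length(e$truth))
      abort_validation("subject '%s': prediction length mismatch",
                       e$subject_id)
    if (rescored) pred <- apply_rescoring(pred)
    m <- epoch_metrics(pred, e$truth)
    out <- list(accuracy = m$accuracy, specificity = m$specificity,
                precision = m$precision, sensitivity = m$sensitivity,
                f1 = m$f1)
    if (is_night) {
      out$waso <- waso(pred, e$truth, e$epoch_length_s)
      out$waso_truth <- waso(e$truth, e$truth, e$epoch_length_s)
      out$sleep_eff <- sleep_efficiency(pred)
      out$sleep_eff_truth <- sleep_efficiency(e$truth)
    }
    out
  })
  as.data.frame(do.call(rbind, lapply(per, function(x)
    unlist(x))), stringsAsFactors = FALSE)
}

.summary_row <- function(method, group, per) {
  row <- list(method = method, group = group, n = nrow(per))
  for (m in c("accuracy", "specificity", "precision", "sensitivity", "f1")) {
    cs <- cohort_summary(per[[m]])
    row[[paste0(m, "_mean")]] <- cs$mean
    row[[paste0(m, "_ci")]] <- cs$ci_halfwidth
  }
  if ("waso" %in% names(per)) {
    cs <- cohort_summary(per$waso, per$waso_truth)
    row$waso_mean <- cs$mean; row$waso_ci <- cs$ci_halfwidth
    row$mae_waso <- cs$mae
    cs <- cohort_summary(per$sleep_eff, per$sleep_eff_truth)
    row$sleep_eff_mean <- cs$mean; row$sleep_eff_ci <- cs$ci_halfwidth
    row$mae_sleep_eff <- cs$mae
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Run the cohort benchmark
#'
#' Evaluates each method (and, when `rescore = TRUE`, its Webster-rescored
#' variant) per subject, summarizes metrics across subjects (mean and 95%
#' confidence half-width), sorts methods within groups by mean accuracy, and
#' tests each method against each baseline with paired two-tailed t-tests on
#' per-subject accuracy and F1. For the night task a ground-truth oracle row
#' is included (exposing the cohort's true WASO and sleep efficiency) along
#' with the WASO / sleep-efficiency mean absolute errors per method.
#'
#' @param task_entries A task dataset from [build_task()] (needs at least 2
#'   subjects for confidence intervals).
#' @param methods Named list of predictors: functions of a `task_entry`
#'   returning a hypnogram, or registered scorer names (see
#'   [list_scorers()]).
#' @param rescore Also report each method's rescored variant (prefix
#'   `"Resc. "`).
#' @param baselines Baseline names to include (default all four).
#' @return List of class `benchmark_result`: `summary` (one row per method),
#'   `significance` (list of p-value matrices for accuracy and F1),
#'   `per_subject` (per-method data frames) and `manifest`.
#' @export
run_benchmark <- function(task_entries, methods, rescore = FALSE,
                          baselines = c("always_sleep", "always_wake",
                                        "device", "manual")) {
  if (length(task_entries) < 2L)
    abort_validation("need at least 2 subjects for cohort summaries")
  if (length(methods) == 0L)
    abort_config("no methods to benchmark")
  task <- attr(task_entries, "task") %||% task_entries[[1]]$task
  is_night <- task == "night"
  if (is.null(names(methods)) && is.character(methods))
    methods <- stats::setNames(as.list(methods), methods)
  if (is.null(names(methods)))
    abort_config("methods must be named")

  runs <- list()  # name -> list(group, per)
  if (is_night) {
    per <- .eval_method(task_entries, function(e) e$truth, TRUE, FALSE)
    runs[["Ground truth"]] <- list(group = "oracle", per = per)
  }
  for (b in baselines) {
    fn <- make_baseline(b)
    nm <- c(always_sleep = "Always sleep", always_wake = "Always wake",
            device = "Device algorithm", manual = "Manual annotation")[b]
    runs[[nm]] <- list(group = "baseline",
                       per = .eval_method(task_entries, fn, is_night, FALSE))
  }
  for (nm in names(methods)) {
    fn <- .as_predictor(methods[[nm]])
    runs[[nm]] <- list(group = "method",
                       per = .eval_method(task_entries, fn, is_night, FALSE))
    if (rescore)
      runs[[paste("Resc.", nm)]] <-
        list(group = "rescored",
             per = .eval_method(task_entries, fn, is_night, TRUE))
  }

  summary <- do.call(rbind, lapply(names(runs), function(nm)
    .summary_row(nm, runs[[nm]]$group, runs[[nm]]$per)))
  grp_order <- c("oracle", "baseline", "method", "rescored")
  summary <- summary[order(match(summary$group, grp_order),
                           -summary$accuracy_mean), ]
  rownames(summary) <- NULL

  base_names <- intersect(names(runs),
                          c("Always sleep", "Always wake", "Device algorithm",
                            "Manual annotation"))
  meth_names <- setdiff(names(runs), c(base_names, "Ground truth"))
  sig <- lapply(c(accuracy = "accuracy", f1 = "f1"), function(metric) {
    m <- matrix(NA_real_, length(meth_names), length(base_names),
                dimnames = list(meth_names, base_names))
    for (i in meth_names) for (j in base_names)
      m[i, j] <- paired_ttest(runs[[i]]$per[[metric]],
                              runs[[j]]$per[[metric]])
    m
  })

  structure(list(summary = summary, significance = sig,
                 per_subject = lapply(runs, `[[`, "per"),
                 manifest = list(task = task,
                                 n_subjects = length(task_entries),
                                 rescore = rescore,
                                 methods = names(methods),
                                 baselines = baselines,
                                 timestamp = format(Sys.time(), tz = "UTC"))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, digits = 1, ...) {
  cat(sprintf("<benchmark_result> task %s, %d subjects, %d rows\n",
              x$manifest$task, x$manifest$n_subjects, nrow(x$summary)))
  cols <- intersect(c("method", "group", "accuracy_mean", "f1_mean",
                      "waso_mean", "mae_waso", "sleep_eff_mean",
                      "mae_sleep_eff"), names(x$summary))
  print(format(x$summary[, cols], digits = digits + 2), row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report
#'
#' Writes the summary as delimited text and the full result (summary,
#' significance matrices, manifest) as a structured JSON report.
#'
#' @param result A `benchmark_result`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_benchmark_report <- function(result, csv_path = NULL,
                                   json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(result$summary, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(summary = result$summary,
           significance = lapply(result$significance, function(m)
             as.data.frame(as.table(m))),
           manifest = result$manifest),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
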