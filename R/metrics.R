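# Evaluation metrics: epoch-level confusion metrics (sleep = positive
# class), clinical sleep-quality metrics (WASO, sleep efficiency), cohort
# summaries with 95% confidence intervals and mean absolute errors, paired
# t-tests, and metric-metric Pearson correlations.

#' Epoch-level confusion metrics
#'
#' Sleep (1) is the positive class. Epochs where either vector is missing
#' are excluded. Any metric with a zero denominator is defined as 0 (an
#' always-wake prediction has precision, sensitivity and F1 of 0).
#'
#' @param pred,truth Aligned binary hypnograms.
#' @return Object of class `epoch_metrics`: percentages `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1` and counts `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
epoch_metrics <- function(pred, truth) {
  pred <- as_hypnogram(pred)
  truth <- as_hypnogram(truth)
  if (length(pred) != length(truth))
    abort_validation("pred and truth have different lengths")
  ok <- !is.na(pred) & !is.na(truth)
  if (!any(ok))
    abort_validation("no jointly non-missing epochs")
  p <- pred[ok]; t <- truth[ok]
  tp <- sum(p == 1L & t == 1L)
  fp <- sum(p == 1L & t == 0L)
  tn <- sum(p == 0L & t == 0L)
  fn <- sum(p == 0L & t == 1L)
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  sens <- pct(tp, tp + fn)
  prec <- pct(tp, tp + fp)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  structure(list(accuracy = pct(tp + tn, tp + fp + tn + fn),
                 sensitivity = sens,
                 specificity = pct(tn, tn + fp),
                 precision = prec, f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "epoch_metrics")
}

#' @export
print.epoch_metrics <- function(x, ...) {
  cat(sprintf("<epoch_metrics> acc %.1f | sens %.1f | spec %.1f | prec %.1f | F1 %.1f (n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1,
              x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Wake after sleep onset (WASO)
#'
#' Sleep onset is the first epoch the ground truth scores as sleep; WASO is
#' the number of predicted-wake epochs strictly after the onset epoch,
#' converted to minutes.
#'
#' @param pred Predicted hypnogram.
#' @param truth Ground-truth hypnogram (must contain at least one sleep
#'   epoch).
#' @param epoch_length_s Epoch duration in seconds (default 30).
#' @return WASO in minutes.
#' @export
waso <- function(pred, truth, epoch_length_s = 30) {
  pred <- as_hypnogram(pred)
  truth <- as_hypnogram(truth)
  if (length(pred) != length(truth))
    abort_validation("pred and truth have different lengths")
  onset <- which(truth == 1L)[1]
  if (is.na(onset))
    abort_validation("ground truth has no sleep epoch; onset undefined")
  after <- if (onset < length(pred)) pred[(onset + 1L):length(pred)]
           else integer(0)
  sum(after == 0L, na.rm = TRUE) * epoch_length_s / 60
}

#' Sleep efficiency
#'
#' Percentage of epochs scored sleep over the entire record (non-missing
#' predictions).
#'
#' @param pred Predicted hypnogram.
#' @return Percentage in `[0, 100]`.
#' @export
sleep_efficiency <- function(pred) {
  pred <- as_hypnogram(pred)
  if (all(is.na(pred)))
    abort_validation("all predictions missing")
  100 * mean(pred == 1L, na.rm = TRUE)
}

#' Cohort summary of a per-subject metric
#'
#' Mean with a 95% normal-approximation confidence half-width
#' (`1.96 * SD / sqrt(n)`), and the mean absolute error against paired
#' ground-truth values when provided.
#'
#' @param values Numeric vector of per-subject metric values.
#' @param truth_values Optional paired ground-truth values.
#' @return List with `mean`, `ci_halfwidth`, `n` and (when `truth_values`
#'   given) `mae`.
#' @export
cohort_summary <- function(values, truth_values = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L)
    abort_validation("need at least 2 subjects for a confidence interval")
  out <- list(mean = mean(values),
              ci_halfwidth = 1.96 * stats::sd(values) / sqrt(n),
              n = n)
  if (!is.null(truth_values)) {
    if (length(truth_values) != n)
      abort_validation("truth_values length mismatch")
    out$mae <- mean(abs(values - truth_values))
  }
  out
}

#' Paired two-sided t-test
#'
#' Convention for degenerate inputs: identical samples give p = 1; a
#' constant nonzero difference gives p = 0.
#'
#' @param a,b Paired numeric vectors (e.g. per-subject metric values of two
#'   methods over the same test subjects).
#' @return Two-sided p-value.
#' @export
paired_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    abort_validation("paired samples have different lengths")
  if (length(a) < 2L)
    abort_validation("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    return(if (all(d == 0)) 1 else 0)
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Pairwise Pearson correlations between metric columns
#'
#' @param method_table `data.frame` with one row per method; non-numeric
#'   columns are dropped. Constant columns yield `NA` entries.
#' @return Symmetric matrix of Pearson r values.
#' @export
metric_correlations <- function(method_table) {
  num <- method_table[vapply(method_table, is.numeric, logical(1))]
  if (nrow(num) < 3L)
    abort_validation("need at least 3 method rows for correlations")
  suppressWarnings(stats::cor(as.matrix(num), method = "pearson"))
}

#' Published night-task benchmark summary table
#'
#' The packaged reference table of per-method cohort results for the night
#' task on the large synchronized actigraphy/PSG cohort: the ground-truth
#' oracle, four baselines and 36 algorithm rows (traditional, rescored,
#' classical ML and deep-learning methods), with mean accuracy, specificity,
#' precision, sensitivity, F1, WASO, sleep efficiency, and mean absolute
#' errors of the two clinical metrics. Used for metric-metric correlation
#' analysis.
#'
#' @return `data.frame` with 41 rows.
#' @export
night_benchmark_table <- function() {
  path <- system.file("extdata", "task_night_published_results.csv",
                      package = "actisleep", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
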