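# Cohort exclusion filters and the subject-level train/test split.

#' Apply cohort quality filters
#'
#' Drops records that cannot be benchmarked against PSG, mirroring the usual
#' quality screen for synchronized actigraphy/PSG cohorts:
#' \describe{
#'   \item{no_overlap}{no epoch has both an activity count and a PSG stage
#'     (the two recordings did not occur concurrently);}
#'   \item{min_usable}{less than 3 h of usable synchronized data, i.e. epochs
#'     where both a count and a stage are present;}
#'   \item{max_psg}{the PSG window spans more than 16 h.}
#' }
#'
#' @param records List of [epoch_series].
#' @return List with `kept` (the surviving records) and `report` (a
#'   `data.frame` with one row per exclusion: `subject_id`, `rule`).
#' @export
apply_cohort_filters <- function(records) {
  if (inherits(records, "epoch_series")) records <- list(records)
  kept <- list()
  excl_id <- character(0)
  excl_rule <- character(0)
  for (s in records) {
    usable <- if (is.null(s$psg_stage)) 0L else
      sum(!is.na(s$counts) & !is.na(s$psg_stage))
    rule <- NULL
    if (usable == 0L) {
      rule <- "no_overlap"
    } else if (usable * s$epoch_length_s < 3 * 3600) {
      rule <- "min_usable"
    } else if (!is.null(s$psg_window) &&
               (s$psg_window[2] - s$psg_window[1] + 1) * s$epoch_length_s >
               16 * 3600) {
      rule <- "max_psg"
    }
    if (is.null(rule)) {
      kept[[s$subject_id]] <- s
    } else {
      excl_id <- c(excl_id, s$subject_id)
      excl_rule <- c(excl_rule, rule)
    }
  }
  list(kept = kept,
       report = data.frame(subject_id = excl_id, rule = excl_rule,
                           stringsAsFactors = FALSE))
}

#' Split subjects into training and test sets
#'
#' Uniform random split without stratification, deterministic given the id
#' order, fraction and seed. The training-set size is `round(fraction * n)`
#' with half-up rounding, so e.g. 1817 subjects at 0.8 give 1454 train /
#' 363 test.
#'
#' @param ids Character vector of unique subject ids.
#' @param train_fraction Proportion of subjects assigned to training,
#'   strictly between 0 and 1 (default 0.8).
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_split` with fields `train_ids`,
#'   `test_ids`, `seed`, `train_fraction`.
#' @export
split_subjects <- function(ids, train_fraction = 0.8, seed = 1L) {
  ids <- as.character(ids)
  if (length(ids) == 0L)
    abort_validation("no subject ids to split")
  if (anyDuplicated(ids))
    abort_validation("duplicate subject id: '%s'",
                     ids[duplicated(ids)][1])
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    abort_validation("train_fraction must be strictly between 0 and 1")
  n <- length(ids)
  n_train <- as.integer(floor(n * train_fraction + 0.5))  # half-up
  train_pos <- with_seed(seed, sample.int(n, n_train))
  in_train <- seq_len(n) %in% train_pos
  structure(
    list(train_ids = ids[in_train],
         test_ids = ids[!in_train],
         seed = as.integer(seed),
         train_fraction = train_fraction),
    class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$train_fraction,
              x$seed))
  invisible(x)
}
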