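#' Construct an epoch series
#'
#' An epoch series is one subject's aligned per-epoch channels: activity
#' counts, optional PSG sleep-stage codes, and an optional expert sleep/wake
#' annotation, all on a fixed epoch grid (30-s epochs by default).
#'
#' Stage codes follow the usual convention: 0 = wake, 1-4 = NREM stages,
#' 5 = REM. The PSG window is the contiguous span from the first to the last
#' epoch with a non-missing stage; stages must be missing outside it.
#'
#' @param subject_id Identifier (coerced to character).
#' @param counts Numeric vector of nonnegative activity counts; `NA` marks
#'   missing (e.g. off-wrist) epochs.
#' @param psg_stage Optional integer vector of stage codes in `{0..5, NA}`,
#'   aligned with `counts`.
#' @param annotation Optional integer vector of expert sleep(1)/wake(0)
#'   labels, aligned with `counts`.
#' @param epoch_length_s Epoch duration in seconds (default 30).
#' @param start_time Optional `POSIXct` timestamp of epoch 0.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(subject_id, counts, psg_stage = NULL,
                         annotation = NULL, epoch_length_s = 30,
                         start_time = NULL) {
  subject_id <- as.character(subject_id)[1]
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 1L)
    abort_validation("epoch series '%s' has no epochs", subject_id)
  if (!is.numeric(epoch_length_s) || length(epoch_length_s) != 1L ||
      is.na(epoch_length_s) || epoch_length_s <= 0)
    abort_validation("epoch_length_s must be a positive number")
  if (any(counts < 0, na.rm = TRUE))
    abort_validation("subject '%s': negative activity counts", subject_id)

  if (!is.null(psg_stage)) {
    psg_stage <- as.integer(psg_stage)
    if (length(psg_stage) != n)
      abort_validation("subject '%s': psg_stage length %d != counts length %d",
                       subject_id, length(psg_stage), n)
    bad <- !is.na(psg_stage) & !(psg_stage %in% 0:5)
    if (any(bad))
      abort_validation("subject '%s': stage codes outside {0..5, NA} at epoch %d",
                       subject_id, which(bad)[1] - 1L)
  }
  if (!is.null(annotation)) {
    annotation <- as.integer(annotation)
    if (length(annotation) != n)
      abort_validation("subject '%s': annotation length mismatch", subject_id)
    if (!is_binary_or_na(annotation))
      abort_validation("subject '%s': annotation values outside {0, 1, NA}",
                       subject_id)
  }

  psg_window <- NULL
  if (!is.null(psg_stage) && any(!is.na(psg_stage))) {
    idx <- which(!is.na(psg_stage))
    psg_window <- c(first = idx[1] - 1L, last = idx[length(idx)] - 1L)
  }

  structure(
    list(subject_id = subject_id,
         epoch_length_s = as.numeric(epoch_length_s),
         start_time = start_time,
         counts = counts,
         psg_stage = psg_stage,
         annotation = annotation,
         psg_window = psg_window),
    class = "epoch_series")
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d epochs x %gs\n",
              x$subject_id, length(x), x$epoch_length_s))
  if (!is.null(x$psg_window))
    cat(sprintf("  PSG window: epochs [%d, %d] (%.1f h)\n",
                x$psg_window[1], x$psg_window[2],
                diff(x$psg_window + c(0, 1)) * x$epoch_length_s / 3600))
  invisible(x)
}

#' Validate a binary hypnogram
#'
#' A hypnogram is a per-epoch vector of sleep/wake labels: 1 = sleep,
#' 0 = wake, `NA` = missing.
#'
#' @param labels Vector coercible to integer with values in `{0, 1, NA}`.
#' @return The validated integer vector.
#' @export
as_hypnogram <- function(labels) {
  labels <- as.integer(labels)
  if (!is_binary_or_na(labels))
    abort_validation("hypnogram labels must be 0, 1 or NA")
  labels
}

#' Collapse PSG stages to a binary hypnogram
#'
#' Stage 0 (wake) maps to 0; stages 1-4 (NREM) and 5 (REM) all map to
#' sleep (1); missing stages stay missing.
#'
#' @param x An `epoch_series`, or an integer vector of stage codes.
#' @return Integer hypnogram of the same length.
#' @export
stages_to_hypnogram <- function(x) {
  stages <- if (inherits(x, "epoch_series")) x$psg_stage else as.integer(x)
  if (is.null(stages))
    abort_validation("no PSG stage channel present")
  bad <- !is.na(stages) & !(stages %in% 0:5)
  if (any(bad))
    abort_validation("stage code outside {0..5, NA} at epoch %d",
                     which(bad)[1] - 1L)
  out <- ifelse(is.na(stages), NA_integer_, as.integer(stages > 0L))
  out
}
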