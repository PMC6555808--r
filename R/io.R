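# Epoch-table I/O.
#
# Native layout: delimited text (CSV), one row per epoch, header required,
# columns subject_id, epoch_idx, timestamp (ISO-8601 or empty), activity,
# stage, annotation; missing values encoded as empty fields. Other layouts
# (e.g. the MESA Sleep "overlap" files) are supported through registered
# column-mapping dialects.

.dialects <- new.env(parent = emptyenv())

#' Register an epoch-table dialect
#'
#' A dialect maps a foreign column layout onto the native one. The mapper
#' receives the raw `data.frame` as read from disk and must return a
#' `data.frame` with columns `subject_id`, `epoch_idx`, `timestamp`,
#' `activity`, `stage`, `annotation` (missing as `NA`).
#'
#' @param name Dialect name.
#' @param mapper Function of one argument as described above.
#' @export
register_dialect <- function(name, mapper) {
  stopifnot(is.character(name), length(name) == 1L, is.function(mapper))
  assign(name, mapper, envir = .dialects)
  invisible(name)
}

#' List registered epoch-table dialects
#' @return Character vector of dialect names.
#' @export
list_dialects <- function() sort(ls(.dialects))

.map_native <- function(df) {
  need <- c("subject_id", "epoch_idx", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("native table is missing required column(s): %s",
                     paste(miss, collapse = ", "))
  data.frame(
    subject_id = as.character(df$subject_id),
    epoch_idx = as.integer(df$epoch_idx),
    timestamp = if ("timestamp" %in% names(df)) as.character(df$timestamp)
                else NA_character_,
    activity = as.numeric(df$activity),
    stage = if ("stage" %in% names(df)) as.integer(df$stage) else NA_integer_,
    annotation = if ("annotation" %in% names(df)) as.integer(df$annotation)
                 else NA_integer_,
    stringsAsFactors = FALSE)
}

# MESA Sleep overlap layout: mesaid, linetime, activity, stage (PSG stage,
# 0 = wake .. 5 = REM), interval (ACTIVE / REST / REST-S / EXCLUDED; the
# expert rest annotation), wake (device algorithm output, not used here).
.map_mesa <- function(df) {
  need <- c("mesaid", "activity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_validation("mesa table is missing required column(s): %s",
                     paste(miss, collapse = ", "))
  ann <- rep(NA_integer_, nrow(df))
  if ("interval" %in% names(df)) {
    iv <- toupper(trimws(as.character(df$interval)))
    ann[iv == "ACTIVE"] <- 0L
    ann[iv %in% c("REST", "REST-S")] <- 1L
  }
  idx <- if ("line" %in% names(df)) as.integer(df$line) else {
    stats::ave(seq_len(nrow(df)), as.character(df$mesaid),
               FUN = seq_along) - 1L
  }
  data.frame(
    subject_id = as.character(df$mesaid),
    epoch_idx = idx,
    timestamp = if ("linetime" %in% names(df)) as.character(df$linetime)
                else NA_character_,
    activity = as.numeric(df$activity),
    stage = if ("stage" %in% names(df)) as.integer(df$stage) else NA_integer_,
    annotation = ann,
    stringsAsFactors = FALSE)
}

register_dialect("native", .map_native)
register_dialect("mesa", .map_mesa)

#' Read an epoch table
#'
#' Reads a delimited epoch-level table and returns one [epoch_series] per
#' subject. Epochs are ordered by index; the PSG window is inferred as the
#' contiguous span of non-missing stage codes.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Name of a registered column mapping (default `"native"`).
#' @param epoch_length_s Epoch duration in seconds (default 30).
#' @return Named list of `epoch_series`, one per subject id.
#' @export
read_epoch_table <- function(path, dialect = "native", epoch_length_s = 30) {
  if (!file.exists(path))
    abort_validation("file not found: %s", path)
  if (!exists(dialect, envir = .dialects))
    abort_config("unknown epoch-table dialect '%s' (registered: %s)",
                 dialect, paste(list_dialects(), collapse = ", "))
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  df <- get(dialect, envir = .dialects)(raw)

  out <- list()
  for (sid in unique(df$subject_id)) {
    rows <- df[df$subject_id == sid, , drop = FALSE]
    ord <- order(rows$epoch_idx)
    if (anyNA(rows$epoch_idx))
      abort_validation("subject '%s': missing epoch index (row %d)",
                       sid, which(is.na(rows$epoch_idx))[1])
    rows <- rows[ord, , drop = FALSE]
    if (anyDuplicated(rows$epoch_idx)) {
      dup <- rows$epoch_idx[duplicated(rows$epoch_idx)][1]
      abort_validation("subject '%s': duplicated epoch index %d", sid, dup)
    }
    ts <- rows$timestamp[!is.na(rows$timestamp)]
    if (length(ts) == nrow(rows) && nrow(rows) > 1L) {
      tt <- suppressWarnings(as.POSIXct(rows$timestamp, tz = "UTC",
                                        format = "%Y-%m-%dT%H:%M:%S"))
      if (!anyNA(tt)) {
        if (anyDuplicated(tt))
          abort_validation("subject '%s': duplicated timestamp at row %d",
                           sid, which(duplicated(tt))[1])
        if (is.unsorted(tt))
          abort_validation("subject '%s': non-monotone timestamps at row %d",
                           sid, which(diff(as.numeric(tt)) < 0)[1] + 1L)
      }
    }
    start_time <- NULL
    if (!is.na(rows$timestamp[1])) {
      st <- suppressWarnings(as.POSIXct(rows$timestamp[1], tz = "UTC",
                                        format = "%Y-%m-%dT%H:%M:%S"))
      if (!is.na(st)) start_time <- st
    }
    out[[sid]] <- epoch_series(sid, rows$activity, psg_stage = rows$stage,
                               annotation = rows$annotation,
                               epoch_length_s = epoch_length_s,
                               start_time = start_time)
  }
  out
}

#' Write epoch series in the native table layout
#'
#' @param x An `epoch_series` or a list of them.
#' @param path Output file path.
#' @param predictions Optional hypnogram (or named list of hypnograms, one
#'   per subject) written as an extra `prediction` column.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(x, path, predictions = NULL) {
  if (inherits(x, "epoch_series")) x <- list(x)
  if (!is.null(predictions) && !is.list(predictions))
    predictions <- list(predictions)
  frames <- lapply(seq_along(x), function(i) {
    s <- x[[i]]
    n <- length(s)
    ts <- rep(NA_character_, n)
    if (!is.null(s$start_time))
      ts <- format(s$start_time + (seq_len(n) - 1L) * s$epoch_length_s,
                   "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    df <- data.frame(
      subject_id = s$subject_id,
      epoch_idx = seq_len(n) - 1L,
      timestamp = ts,
      activity = s$counts,
      stage = if (is.null(s$psg_stage)) NA_integer_ else s$psg_stage,
      annotation = if (is.null(s$annotation)) NA_integer_ else s$annotation,
      stringsAsFactors = FALSE)
    if (!is.null(predictions)) {
      p <- if (!is.null(names(predictions))) predictions[[s$subject_id]]
           else predictions[[i]]
      if (!is.null(p)) {
        if (length(p) != n)
          abort_validation("subject '%s': prediction length mismatch",
                           s$subject_id)
        df$prediction <- as.integer(p)
      }
    }
    df
  })
  utils::write.csv(do.call(rbind, frames), path, row.names = FALSE, na = "")
  invisible(path)
}
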