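# Sliding-window summary-statistic features for classical classifiers.
#
# For each epoch the schema collects the raw count and its natural log
# (log1p), plus summary statistics of sliding windows around the epoch:
# a centered window of N epochs each side (2N+1 values) and a trailing
# window of the N preceding epochs plus the current one (N+1 values), for
# N = 1..19. Out-of-range positions are zero-filled by default, matching
# the actigraph's "no movement" reading.

.stats_full <- c("mean", "median", "std", "var", "min", "max", "sum",
                 "range", "iqr", "nonzero_prop")
.stats_small <- c("mean", "min", "max", "sum")

#' Default feature schema
#'
#' Base features `raw` and `log1p` plus window statistics for
#' N = 1..19 and both window types. The smallest windows (N = 1) carry only
#' the four location/extreme statistics (mean, min, max, sum) because
#' spread and quantile statistics are near-degenerate on 2-3 values; all
#' larger windows carry the full ten-statistic set. The default totals
#' exactly 370 features.
#'
#' @return Object of class `feature_schema` with fields `base_features`,
#'   `grid` (one row per window/type with its statistic list) and `total`.
#' @export
default_schema <- function() {
  grid <- expand.grid(window = 1:19,
                      type = c("centered", "trailing"),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$window, grid$type), ]
  rownames(grid) <- NULL
  grid$stats <- lapply(grid$window,
                       function(N) if (N == 1L) .stats_small else .stats_full)
  feature_schema(base_features = c("raw", "log1p"), grid = grid)
}

#' Construct a feature schema
#'
#' @param base_features Subset of `c("raw", "log1p")`.
#' @param grid `data.frame` with columns `window` (positive integer), `type`
#'   (`"centered"` or `"trailing"`) and a list-column `stats` of statistic
#'   names per window.
#' @param boundary Boundary policy: `"zero"` (zero-fill, default) or
#'   `"truncate"` (shrink boundary windows to the available epochs).
#' @return Object of class `feature_schema`.
#' @export
feature_schema <- function(base_features = c("raw", "log1p"), grid,
                           boundary = c("zero", "truncate")) {
  boundary <- match.arg(boundary)
  if (!all(base_features %in% c("raw", "log1p")))
    abort_config("base_features must be a subset of {raw, log1p}")
  known <- .stats_full
  for (s in grid$stats) {
    bad <- setdiff(s, known)
    if (length(bad))
      abort_config("unknown statistic name(s): %s", paste(bad, collapse = ", "))
  }
  if (any(grid$window < 1L))
    abort_config("window sizes must be >= 1")
  cols <- c(base_features,
            unlist(Map(function(N, type, stats)
              paste0(stats, "_", type, "_w", N),
              grid$window, grid$type, grid$stats)))
  structure(list(base_features = base_features, grid = grid,
                 boundary = boundary, columns = cols,
                 total = length(cols)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d features (%d base + %d window stats), %s boundary\n",
              x$total, length(x$base_features),
              x$total - length(x$base_features), x$boundary))
  invisible(x)
}

.window_stat <- function(W, stat) {
  switch(stat,
         mean = rowMeans(W),
         median = apply(W, 1L, stats::median),
         std = {
           m1 <- rowMeans(W)
           sqrt(pmax(rowSums((W - m1)^2) / (ncol(W) - 1L), 0))
         },
         var = {
           m1 <- rowMeans(W)
           pmax(rowSums((W - m1)^2) / (ncol(W) - 1L), 0)
         },
         min = do.call(pmin, as.data.frame(W)),
         max = do.call(pmax, as.data.frame(W)),
         sum = rowSums(W),
         range = do.call(pmax, as.data.frame(W)) -
           do.call(pmin, as.data.frame(W)),
         iqr = apply(W, 1L, stats::IQR),
         nonzero_prop = rowMeans(W != 0),
         abort_config("unknown statistic '%s'", stat))
}

# Truncate-policy variant: positions outside the record are dropped from the
# window rather than zero-filled.
.window_stat_trunc <- function(x, before, after, stat) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    w <- x[max(1L, t - before):min(n, t + after)]
    switch(stat,
           mean = mean(w), median = stats::median(w),
           std = if (length(w) > 1L) stats::sd(w) else 0,
           var = if (length(w) > 1L) stats::var(w) else 0,
           min = min(w), max = max(w), sum = sum(w),
           range = max(w) - min(w), iqr = stats::IQR(w),
           nonzero_prop = mean(w != 0))
  }, numeric(1))
}

#' Extract sliding-window features
#'
#' @param counts Numeric vector of activity counts. Missing counts are
#'   treated as 0 for feature computation (the epochs are flagged so that
#'   downstream predictions can stay missing).
#' @param schema A `feature_schema`, by default [default_schema()].
#' @return Numeric matrix with one row per epoch and `schema$total` columns,
#'   with attribute `own_missing` marking epochs whose own count was missing
#'   and attribute `schema` carrying the schema.
#' @examples
#' f <- extract_features(c(1, 2, 3))
#' ncol(f)  # 370
#' @export
extract_features <- function(counts, schema = default_schema()) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    abort_validation("empty count sequence")
  own_missing <- is.na(counts)
  x <- ifelse(own_missing, 0, counts)
  n <- length(x)
  out <- matrix(0, nrow = n, ncol = schema$total,
                dimnames = list(NULL, schema$columns))
  if ("raw" %in% schema$base_features) out[, "raw"] <- x
  if ("log1p" %in% schema$base_features) out[, "log1p"] <- log1p(x)
  for (j in seq_len(nrow(schema$grid))) {
    N <- schema$grid$window[j]
    type <- schema$grid$type[j]
    stats_j <- schema$grid$stats[[j]]
    before <- N
    after <- if (type == "centered") N else 0L
    if (schema$boundary == "zero") {
      W <- .window_mat(x, before, after)
      for (s in stats_j)
        out[, paste0(s, "_", type, "_w", N)] <- .window_stat(W, s)
    } else {
      for (s in stats_j)
        out[, paste0(s, "_", type, "_w", N)] <-
          .window_stat_trunc(x, before, after, s)
    }
  }
  attr(out, "own_missing") <- own_missing
  attr(out, "schema") <- schema
  out
}

#' Write a feature matrix as delimited text
#'
#' @param features Matrix from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
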