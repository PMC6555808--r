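# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Naive double-loop evaluation of a weighted-sum scorer.
naive_weighted_sum <- function(counts, weights, scale) {
  offs <- as.integer(names(weights))
  n <- length(counts)
  vapply(seq_len(n), function(t) {
    s <- 0
    for (k in seq_along(offs)) {
      j <- t + offs[k]
      v <- if (j >= 1 && j <= n && !is.na(counts[j])) counts[j] else 0
      s <- s + weights[[k]] * v
    }
    scale * s
  }, numeric(1))
}

# Explicit per-epoch scanning interpreter for Webster's rules: for every
# sleep epoch it walks outwards to measure its run and the flanking wake
# runs on the pass input, then applies the rule text directly.
brute_rescore <- function(labels, flank_mode = "or") {
  n <- length(labels)
  is1 <- function(x, j) j >= 1 && j <= n && !is.na(x[j]) && x[j] == 1
  is0 <- function(x, j) j >= 1 && j <= n && !is.na(x[j]) && x[j] == 0
  for (rule in list(c(4, 1), c(10, 3), c(15, 4))) {
    out <- labels
    for (t in seq_len(n)) {
      if (!is1(labels, t)) next
      a <- t
      while (is1(labels, a - 1)) a <- a - 1
      if (t - a + 1 > rule[2]) next
      w <- 0; j <- a - 1
      while (is0(labels, j)) { w <- w + 1; j <- j - 1 }
      if (w >= rule[1]) out[t] <- 0L
    }
    labels <- out
  }
  for (rule in list(c(6, 10), c(10, 20))) {
    out <- labels
    for (t in seq_len(n)) {
      if (!is1(labels, t)) next
      a <- t; while (is1(labels, a - 1)) a <- a - 1
      b <- t; while (is1(labels, b + 1)) b <- b + 1
      if (b - a + 1 > rule[1]) next
      wl <- 0; j <- a - 1
      while (is0(labels, j)) { wl <- wl + 1; j <- j - 1 }
      wr <- 0; j <- b + 1
      while (is0(labels, j)) { wr <- wr + 1; j <- j + 1 }
      hit <- if (flank_mode == "and") wl >= rule[2] && wr >= rule[2]
             else wl >= rule[2] || wr >= rule[2]
      if (hit) out[t] <- 0L
    }
    labels <- out
  }
  labels
}

# Naive epoch-by-epoch confusion counter.
naive_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (is.na(pred[i]) || is.na(truth[i])) next
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Random count vector with optional missing epochs.
random_counts <- function(n, na_prob = 0.1) {
  x <- stats::rexp(n, rate = 1 / 80)
  x[stats::runif(n) < na_prob] <- NA
  x
}

# Small fully-specified epoch series for I/O and task tests.
toy_series <- function(subject_id = "T1", n = 60, psg = c(10, 49),
                       seed = 1) {
  set.seed(seed)
  counts <- round(stats::rexp(n, 1 / 50), 2)
  stage <- rep(NA_integer_, n)
  stage[(psg[1]:psg[2]) + 1L] <- sample(0:5, diff(psg) + 1L, replace = TRUE)
  ann <- stats::rbinom(n, 1L, 0.4)
  epoch_series(subject_id, counts, psg_stage = stage, annotation = ann,
               start_time = as.POSIXct("2000-01-01 22:00:00", tz = "UTC"))
}
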