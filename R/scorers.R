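# Traditional sleep-wake scoring algorithms.
#
# All six classical scorers reduce to a per-epoch real score compared
# against a cut-off. Webster, Cole-Kripke, Oakley and Scripps Clinic are
# weighted sums of activity counts over a fixed offset window; Sadeh is a
# linear model on window summary statistics; Sazonov is a causal linear
# model on rolling count maxima. Coefficients are kept in a registry so the
# published parameterizations stay in one auditable place and users can
# register their own.

.sleep_when_rules <- c("score_lt_threshold", "score_ge_threshold",
                       "score_le_threshold")

#' Build a scorer specification
#'
#' @param name Algorithm identifier.
#' @param kind One of `"weighted_sum"`, `"sadeh"`, `"sazonov"`.
#' @param weights Named numeric vector: names are integer epoch offsets
#'   (e.g. `-4` .. `2`), values the per-offset coefficients. For
#'   `kind = "sazonov"` the offsets `0, -1, ..` index rolling-maximum window
#'   sizes 1, 2, .. instead.
#' @param scale Multiplicative factor applied to the weighted sum.
#' @param threshold Decision cut-off.
#' @param sleep_when Decision rule, one of `"score_lt_threshold"`,
#'   `"score_ge_threshold"`, `"score_le_threshold"`.
#' @param params Extra algorithm parameters (used by Sadeh).
#' @param source Free-text provenance note for the coefficient set.
#' @return Object of class `scorer_spec`.
#' @export
scorer_spec <- function(name, kind, weights = NULL, scale = 1,
                        threshold = 1, sleep_when = "score_lt_threshold",
                        params = list(), source = "") {
  if (!kind %in% c("weighted_sum", "sadeh", "sazonov"))
    abort_config("unknown scorer kind '%s'", kind)
  if (!sleep_when %in% .sleep_when_rules)
    abort_config("unknown sleep_when rule '%s'", sleep_when)
  if (kind != "sadeh") {
    if (is.null(weights) || length(weights) == 0L || is.null(names(weights)))
      abort_config("scorer '%s': weights must be a non-empty named vector",
                   name)
    offs <- suppressWarnings(as.integer(names(weights)))
    if (anyNA(offs))
      abort_config("scorer '%s': weight names must be integer offsets", name)
  }
  if (!is.finite(scale))
    abort_config("scorer '%s': scale must be finite", name)
  offsets <- if (is.null(weights)) integer(0) else as.integer(names(weights))
  structure(
    list(name = name, kind = kind, weights = weights, scale = scale,
         threshold = threshold, sleep_when = sleep_when, params = params,
         causal = length(offsets) > 0 && max(offsets) <= 0L,
         source = source),
    class = "scorer_spec")
}

.decide <- function(scores, sleep_when, threshold) {
  pred <- switch(sleep_when,
                 score_lt_threshold = as.integer(scores < threshold),
                 score_le_threshold = as.integer(scores <= threshold),
                 score_ge_threshold = as.integer(scores >= threshold))
  pred
}

.score_series <- function(scores, counts, spec) {
  pred <- .decide(scores, spec$sleep_when, spec$threshold)
  pred[is.na(counts)] <- NA_integer_  # no count for the epoch itself
  structure(list(scores = scores, predictions = pred, algorithm = spec$name),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series> %s: %d epochs, %.1f%% scored sleep\n",
              x$algorithm, length(x$scores),
              100 * mean(x$predictions == 1L, na.rm = TRUE)))
  invisible(x)
}

# Shift a vector by `off` epochs, padding with `fill`.
.shift <- function(x, off, fill = 0) {
  n <- length(x)
  if (off == 0L) return(x)
  if (off > 0L) c(x[-seq_len(min(off, n))], rep(fill, min(off, n)))
  else c(rep(fill, min(-off, n)), x[seq_len(max(n + off, 0))])
}

#' Apply a weighted-sum scorer
#'
#' Computes `score_t = scale * sum_i w_i * counts[t + i]`; counts that are
#' missing or outside the record contribute 0. The sleep/wake decision
#' follows the spec's `sleep_when` rule; epochs whose own count is missing
#' get a missing prediction.
#'
#' @param counts Numeric vector of activity counts.
#' @param spec A `scorer_spec` with `kind = "weighted_sum"`.
#' @return Object of class `score_series` with `scores` and `predictions`.
#' @export
apply_weighted_sum_scorer <- function(counts, spec) {
  if (!inherits(spec, "scorer_spec") || spec$kind != "weighted_sum")
    abort_config("spec must be a weighted_sum scorer_spec")
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    abort_validation("empty count sequence")
  filled <- ifelse(is.na(counts), 0, counts)
  offsets <- as.integer(names(spec$weights))
  scores <- numeric(length(counts))
  for (k in seq_along(offsets))
    scores <- scores + spec$weights[[k]] * .shift(filled, offsets[k])
  scores <- spec$scale * scores
  .score_series(scores, counts, spec)
}

# Rolling window matrix: rows = epochs, cols = window positions, built on a
# zero-padded copy so boundary epochs see zeros outside the record.
.window_mat <- function(x, before, after) {
  n <- length(x)
  padded <- c(rep(0, before), x, rep(0, after))
  # embed() returns reversed column order; flip so col 1 = earliest offset
  m <- stats::embed(padded, before + after + 1L)
  m[, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Apply the Sadeh scorer
#'
#' `PS_t = 7.601 - 0.065 AVG - 1.08 NAT - 0.056 SD - 0.703 LG` with
#' AVG = mean count over `[t-5, t+5]`, NAT = number of epochs in that window
#' with count in `[50, 100)`, SD = population standard deviation over
#' `[t-5, t]`, `LG = ln(count_t + 1)`; sleep iff `PS_t >= 0`. Boundary
#' windows are zero-padded; missing counts are excluded from the window
#' denominators.
#'
#' @param counts Numeric vector of activity counts.
#' @param params Optional coefficient overrides (`intercept`, `coef_avg`,
#'   `coef_nat`, `coef_sd`, `coef_lg`, `threshold`).
#' @return Object of class `score_series`.
#' @export
apply_sadeh <- function(counts, params = list()) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    abort_validation("empty count sequence")
  p <- utils::modifyList(list(intercept = 7.601, coef_avg = 0.065,
                              coef_nat = 1.08, coef_sd = 0.056,
                              coef_lg = 0.703, threshold = 0), params)
  w11 <- .window_mat(counts, 5L, 5L)
  avg <- rowMeans(w11, na.rm = TRUE)
  nat <- rowSums(w11 >= 50 & w11 < 100, na.rm = TRUE)
  w6 <- .window_mat(counts, 5L, 0L)
  m1 <- rowMeans(w6, na.rm = TRUE)
  m2 <- rowMeans(w6^2, na.rm = TRUE)
  sdv <- sqrt(pmax(m2 - m1^2, 0))  # population SD, divisor n
  lg <- log(ifelse(is.na(counts), 0, counts) + 1)
  scores <- p$intercept - p$coef_avg * avg - p$coef_nat * nat -
    p$coef_sd * sdv - p$coef_lg * lg
  spec <- scorer_spec("sadeh", "sadeh", weights = c(`0` = 1),
                      threshold = p$threshold,
                      sleep_when = "score_ge_threshold", params = p)
  out <- .score_series(scores, counts, spec)
  out$scores[is.na(counts)] <- NA_real_
  out
}

#' Apply the Sazonov scorer
#'
#' Causal linear score on rolling count maxima:
#' `S_t = intercept - sum_k coef_k * w_k(t)` where `w_k(t)` is the maximum
#' count over the trailing window `[t-k+1, t]` (zero-padded before the
#' record start); sleep iff `S_t >= threshold`. The prediction at epoch `t`
#' depends only on counts at epochs `<= t`.
#'
#' @param counts Numeric vector of activity counts.
#' @param params Optional overrides (`intercept`, `coefs` (one per window
#'   size, longest window = `length(coefs)`), `threshold`).
#' @return Object of class `score_series`.
#' @export
apply_sazonov <- function(counts, params = list()) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L)
    abort_validation("empty count sequence")
  p <- utils::modifyList(list(intercept = 1.727,
                              coefs = c(0.256, 0.154, 0.136, 0.140, 0.176),
                              threshold = 0.5), params)
  filled <- ifelse(is.na(counts), 0, counts)
  scores <- rep(p$intercept, length(counts))
  for (k in seq_along(p$coefs)) {
    wmax <- apply(.window_mat(filled, k - 1L, 0L), 1L, max)
    scores <- scores - p$coefs[k] * wmax
  }
  offs <- -(seq_along(p$coefs) - 1L)
  spec <- scorer_spec("sazonov", "sazonov",
                      weights = stats::setNames(p$coefs, offs),
                      threshold = p$threshold,
                      sleep_when = "score_ge_threshold", params = p)
  out <- .score_series(scores, counts, spec)
  out$scores[is.na(counts)] <- NA_real_
  out
}

# ---- registry -------------------------------------------------------------

.scorer_registry <- new.env(parent = emptyenv())

.register_default_scorers <- function() {
  reg <- function(spec) assign(spec$name, spec, envir = .scorer_registry)

  reg(scorer_spec(
    "webster", "weighted_sum",
    weights = stats::setNames(c(0.15, 0.15, 0.15, 0.08, 0.21, 0.12, 0.13),
                              -4:2),
    scale = 0.025, threshold = 1, sleep_when = "score_lt_threshold",
    source = "Webster et al. 1982; sleep iff scaled sum < 1"))

  reg(scorer_spec(
    "cole_kripke", "weighted_sum",
    weights = stats::setNames(c(106, 54, 58, 76, 230, 74, 67), -4:2),
    scale = 0.001, threshold = 1, sleep_when = "score_lt_threshold",
    source = "Cole et al. 1992; D = 0.001 * weighted sum, sleep iff D < 1"))

  # Actiwatch-style total-count score: 1/25 at +-2 min, 1/5 at +-1 min,
  # 1 at the center epoch, mapped minute-bin-wise onto the 30-s grid;
  # wake iff score > theta, so score == theta scores sleep.
  reg(scorer_spec(
    "oakley", "weighted_sum",
    weights = stats::setNames(
      c(1/25, 1/25, 1/5, 1/5, 1, 1/5, 1/5, 1/25, 1/25), -4:4),
    scale = 1, threshold = 40, sleep_when = "score_le_threshold",
    source = "Oakley 1997 / Actiwatch; theta = 40 is the device default"))

  reg(scorer_spec(
    "scripps", "weighted_sum",
    weights = stats::setNames(
      c(0.0064, 0.0074, 0.0112, 0.0112, 0.0118, 0.0118, 0.0128, 0.0188,
        0.0280, 0.0664, 0.3000, 0.0664, 0.0280, 0.0188, 0.0128, 0.0118,
        0.0118, 0.0112, 0.0112, 0.0074, 0.0064), -10:10),
    scale = 0.204, threshold = 1, sleep_when = "score_lt_threshold",
    source = "Kripke et al. 2010 (Scripps Clinic); sleep iff 0.204 * sum < 1"))

  reg(scorer_spec(
    "sadeh", "sadeh", weights = c(`0` = 1), threshold = 0,
    sleep_when = "score_ge_threshold",
    params = list(intercept = 7.601, coef_avg = 0.065, coef_nat = 1.08,
                  coef_sd = 0.056, coef_lg = 0.703, threshold = 0),
    source = "Sadeh et al. 1994; population-SD convention for the SD term"))

  reg(scorer_spec(
    "sazonov", "sazonov",
    weights = stats::setNames(c(0.256, 0.154, 0.136, 0.140, 0.176), -(0:4)),
    threshold = 0.5, sleep_when = "score_ge_threshold",
    params = list(intercept = 1.727,
                  coefs = c(0.256, 0.154, 0.136, 0.140, 0.176),
                  threshold = 0.5),
    source = "Sazonov et al. 2004; causal rolling maxima, sleep iff S >= 0.5"))
}

.register_default_scorers()

#' List registered scoring algorithms
#' @return Character vector of algorithm names.
#' @export
list_scorers <- function() sort(ls(.scorer_registry))

#' Retrieve a scorer specification from the registry
#' @param name Algorithm name.
#' @return The registered `scorer_spec`.
#' @export
get_scorer <- function(name) {
  if (!exists(name, envir = .scorer_registry))
    abort_config("unknown scoring algorithm '%s' (registered: %s)",
                 name, paste(list_scorers(), collapse = ", "))
  get(name, envir = .scorer_registry)
}

#' Register a custom scorer
#' @param spec A `scorer_spec`.
#' @export
register_scorer <- function(spec) {
  if (!inherits(spec, "scorer_spec"))
    abort_config("register_scorer() expects a scorer_spec")
  assign(spec$name, spec, envir = .scorer_registry)
  invisible(spec$name)
}

#' Export the scorer registry to a JSON config file
#'
#' The file is human-readable and round-trips through
#' [register_scorer()]-compatible specs.
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorer_registry <- function(path) {
  specs <- lapply(list_scorers(), function(nm) {
    s <- get_scorer(nm)
    list(name = s$name, kind = s$kind,
         weights = as.list(s$weights), scale = s$scale,
         threshold = s$threshold, sleep_when = s$sleep_when,
         params = s$params, causal = s$causal, source = s$source)
  })
  jsonlite::write_json(specs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Score a count sequence with a registered algorithm
#'
#' Dispatches to the appropriate scorer with the registry coefficient set,
#' optionally merged with overrides. For `"oakley"` the override `theta`
#' (alias for `threshold`) selects the decision cut-off.
#'
#' @param name Registered algorithm name (see [list_scorers()]).
#' @param counts Numeric vector of activity counts.
#' @param overrides Named list of parameter overrides.
#' @return Object of class `score_series`.
#' @examples
#' score("cole_kripke", c(0, 0, 120, 300, 10, 0))
#' score("oakley", c(0, 50, 200), overrides = list(theta = 40))
#' @export
score <- function(name, counts, overrides = list()) {
  spec <- get_scorer(name)
  if (length(overrides)) {
    ok <- switch(spec$kind,
                 weighted_sum = c("weights", "scale", "threshold",
                                  "sleep_when", "theta"),
                 sadeh = c("intercept", "coef_avg", "coef_nat", "coef_sd",
                           "coef_lg", "threshold"),
                 sazonov = c("intercept", "coefs", "threshold"))
    bad <- setdiff(names(overrides), ok)
    if (length(bad))
      abort_config("invalid override(s) for '%s': %s", name,
                   paste(bad, collapse = ", "))
  }
  if (spec$kind == "weighted_sum") {
    if (!is.null(overrides$theta)) {
      overrides$threshold <- overrides$theta
      overrides$theta <- NULL
    }
    for (f in names(overrides)) spec[[f]] <- overrides[[f]]
    apply_weighted_sum_scorer(counts, spec)
  } else if (spec$kind == "sadeh") {
    apply_sadeh(counts, utils::modifyList(spec$params, overrides))
  } else {
    apply_sazonov(counts, utils::modifyList(spec$params, overrides))
  }
}
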