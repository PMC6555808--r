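# Webster's wake-rescoring rules.
#
# Count-based scorers systematically over-score sleep; Webster's five rules
# flip short sleep runs that sit next to long wake runs back to wake. Rules
# are applied sequentially, one full left-to-right pass each; within a pass
# run lengths are measured on the pass input, so a freshly rescored epoch
# never re-triggers the same rule in the same pass (inter-pass cascading is
# preserved). Missing labels break runs and are never rescored. Only
# sleep-to-wake changes ever occur.

#' Webster's five rescoring rules
#'
#' R1-R3 rescore the first 1/3/4 sleep epochs after wake runs of at least
#' 4/10/15 epochs. R4 and R5 rescore sleep islands of at most 6/10 epochs
#' flanked by a wake run of at least 10/20 epochs. `flank_mode` controls
#' whether one flank suffices (`"or"`, the default) or both are required
#' (`"and"`, Webster's original reading).
#'
#' @param flank_mode `"or"` or `"and"` for rules R4/R5.
#' @return List of five rescoring-rule objects.
#' @export
webster_rules <- function(flank_mode = c("or", "and")) {
  flank_mode <- match.arg(flank_mode)
  after <- function(id, trigger, count)
    list(rule_id = id, type = "after_wake", trigger_wake_run = trigger,
         rescore_count = count)
  island <- function(id, max_island, flank)
    list(rule_id = id, type = "island", max_island = max_island,
         flank_wake_run = flank, flank_mode = flank_mode)
  list(after("R1", 4L, 1L),
       after("R2", 10L, 3L),
       after("R3", 15L, 4L),
       island("R4", 6L, 10L),
       island("R5", 10L, 20L))
}

# One pass of a single rule over fixed input labels; returns modified copy.
.apply_rule_pass <- function(labels, rule) {
  out <- labels
  # Run-length encode with NA as its own symbol (breaks runs).
  sym <- ifelse(is.na(labels), -1L, labels)
  r <- rle(sym)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (rule$type == "after_wake") {
      if (r$values[j] != 0L || r$lengths[j] < rule$trigger_wake_run) next
      if (j == length(r$values) || r$values[j + 1L] != 1L) next
      k <- min(rule$rescore_count, r$lengths[j + 1L])
      out[starts[j + 1L] + seq_len(k) - 1L] <- 0L
    } else {
      if (r$values[j] != 1L || r$lengths[j] > rule$max_island) next
      left <- j > 1L && r$values[j - 1L] == 0L &&
        r$lengths[j - 1L] >= rule$flank_wake_run
      right <- j < length(r$values) && r$values[j + 1L] == 0L &&
        r$lengths[j + 1L] >= rule$flank_wake_run
      hit <- if (rule$flank_mode == "and") left && right else left || right
      if (hit) out[starts[j]:ends[j]] <- 0L
    }
  }
  out
}

#' Apply rescoring rules to a hypnogram
#'
#' @param labels Binary hypnogram (1 = sleep, 0 = wake, `NA` passed through
#'   untouched and treated as a run breaker).
#' @param rules Ordered rule list, by default [webster_rules()].
#' @return Rescored hypnogram of the same length; the number of sleep epochs
#'   never increases.
#' @examples
#' apply_rescoring(c(0, 0, 0, 0, 1, 1, 1))  # R1 flips the first sleep epoch
#' @export
apply_rescoring <- function(labels, rules = webster_rules()) {
  labels <- as.integer(labels)
  if (!is_binary_or_na(labels))
    abort_validation("labels must be 0, 1 or NA")
  for (rule in rules)
    labels <- .apply_rule_pass(labels, rule)
  labels
}
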