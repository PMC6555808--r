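# Internal helpers: error signalling and seeded evaluation.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("actisleep_validation_error", "error")))
}

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("actisleep_config_error", "error")))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

is_binary_or_na <- function(x) {
  all(is.na(x) | x == 0L | x == 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
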