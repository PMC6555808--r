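# Synthetic actigraphy cohort generator.
#
# Each subject is a PSG night (9-12 h by default) flanked by day-time wear
# (4-8 h each side). The hidden sleep/wake path is a two-state semi-Markov
# chain with geometric-mixture dwell times, so consolidated sleep bouts and
# brief awakenings coexist; night and day phases have their own bout-length
# regimes (day sleep = naps). Activity counts are emitted from a per-state
# zero-inflated gamma model: sleep epochs are mostly zero with small
# residual movement, wake epochs are rarely zero with high, dispersed
# counts. An expert-annotation channel equals the hidden state with a
# per-epoch flip probability. Everything is reproducible from the seeds.

#' Simulation configuration
#'
#' Defaults emulate a large PSG-synchronized actigraphy cohort: night sleep
#' fraction 58.4%, PSG length uniform on 9-12 h, day pads uniform on 4-8 h
#' each side with a 6% nap fraction, which yields roughly 69% wake over the
#' full night-and-day record.
#'
#' @param n_subjects Number of subjects.
#' @param epoch_length_s Epoch duration in seconds.
#' @param psg_hours Sampling range (h) of the PSG window length; capped at
#'   16 h so generated cohorts pass [apply_cohort_filters()].
#' @param pad_hours Sampling range (h) of day-time wear on each side of PSG.
#' @param night_sleep_fraction Stationary sleep fraction inside the PSG
#'   window.
#' @param mean_sleep_bout Mean night sleep-bout length (epochs).
#' @param sleep_bout_short_prob,sleep_bout_short_mean Geometric-mixture
#'   short component of night sleep bouts (probability and mean epochs); the
#'   long-component mean is derived to preserve `mean_sleep_bout`.
#' @param wake_bout_short_prob,wake_bout_short_mean Same for night wake
#'   bouts (brief awakenings vs long lights-on wake); the overall mean wake
#'   bout is derived from `night_sleep_fraction`.
#' @param day_sleep_fraction Stationary sleep (nap) fraction during day
#'   phases.
#' @param day_mean_nap Mean nap length (epochs).
#' @param sleep_zero_prob,sleep_count_mean,sleep_count_shape Zero-inflation
#'   probability and gamma parameters of nonzero counts in sleep epochs.
#' @param wake_zero_prob,wake_count_mean,wake_count_shape Same for wake.
#' @param annotation_flip_prob Per-epoch flip probability of the simulated
#'   expert channel relative to the hidden state.
#' @param seed Master integer seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 10L,
                              epoch_length_s = 30,
                              psg_hours = c(9, 12),
                              pad_hours = c(4, 8),
                              night_sleep_fraction = 0.584,
                              mean_sleep_bout = 90,
                              sleep_bout_short_prob = 0.3,
                              sleep_bout_short_mean = 20,
                              wake_bout_short_prob = 0.75,
                              wake_bout_short_mean = 4,
                              day_sleep_fraction = 0.06,
                              day_mean_nap = 30,
                              sleep_zero_prob = 0.85,
                              sleep_count_mean = 5,
                              sleep_count_shape = 0.7,
                              wake_zero_prob = 0.30,
                              wake_count_mean = 150,
                              wake_count_shape = 1.0,
                              annotation_flip_prob = 0.02,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(night_sleep_fraction, day_sleep_fraction, sleep_bout_short_prob,
             wake_bout_short_prob, sleep_zero_prob, wake_zero_prob,
             annotation_flip_prob)
  if (any(probs < 0 | probs > 1))
    abort_config("all probabilities must lie in [0, 1]")
  if (any(c(sleep_count_mean, sleep_count_shape, wake_count_mean,
            wake_count_shape) <= 0))
    abort_config("gamma emission parameters must be positive")
  if (max(psg_hours) > 16)
    abort_config("psg_hours must not exceed 16 h")
  if (n_subjects < 1L)
    abort_config("n_subjects must be >= 1")

  # Derived mixture components: the long-component means preserve the
  # configured overall bout means; the mean wake bout preserves the
  # configured stationary sleep fraction of each phase.
  f <- night_sleep_fraction
  cfg$night_mean_wake_bout <- mean_sleep_bout * (1 - f) / f
  cfg$sleep_bout_long_mean <-
    (mean_sleep_bout - sleep_bout_short_prob * sleep_bout_short_mean) /
    (1 - sleep_bout_short_prob)
  cfg$wake_bout_long_mean <-
    (cfg$night_mean_wake_bout - wake_bout_short_prob * wake_bout_short_mean) /
    (1 - wake_bout_short_prob)
  fd <- day_sleep_fraction
  cfg$day_mean_wake_bout <- day_mean_nap * (1 - fd) / fd
  if (cfg$sleep_bout_long_mean < 1 || cfg$wake_bout_long_mean < 1)
    abort_config("bout mixture parameters imply a long-component mean < 1")
  structure(cfg, class = "simulation_config")
}

# Geometric dwell with a given mean (>= 1 epoch).
.rdwell <- function(mean_epochs) {
  stats::rgeom(1L, prob = min(1, 1 / mean_epochs)) + 1L
}

# Mean dwell for the next bout. Geometric dwells are memoryless, so the
# stationary residual of a mixture bout differs from a fresh draw only in
# the component weights: the first bout of a segment uses length-biased
# component probabilities, which makes the within-segment state process
# exactly stationary (the realized sleep fraction is unbiased for the
# configured one).
.dwell_mean <- function(cfg, state, phase, stationary = FALSE) {
  if (phase == "night") {
    if (state == 1L) {
      p <- cfg$sleep_bout_short_prob
      ms <- cfg$sleep_bout_short_mean
      ml <- cfg$sleep_bout_long_mean
    } else {
      p <- cfg$wake_bout_short_prob
      ms <- cfg$wake_bout_short_mean
      ml <- cfg$wake_bout_long_mean
    }
    if (stationary) p <- p * ms / (p * ms + (1 - p) * ml)
    if (stats::runif(1) < p) ms else ml
  } else {
    if (state == 1L) cfg$day_mean_nap else cfg$day_mean_wake_bout
  }
}

#' Generate one synthetic subject
#'
#' @param config A [simulation_config()].
#' @param subject_seed Integer; together with `config$seed` it fully
#'   determines the subject (the per-subject stream seed is
#'   `config$seed * 69091 + subject_seed`, reduced mod 2^31 - 1).
#' @param subject_id Identifier (default derived from `subject_seed`).
#' @return An [epoch_series] with counts, PSG stages inside the PSG window
#'   (hidden sleep states get stage codes 1-5 uniformly, wake gets 0), an
#'   annotation channel over the full record, and an extra `hidden_state`
#'   field with the simulated truth.
#' @export
generate_subject <- function(config, subject_seed,
                             subject_id = sprintf("S%04d", subject_seed)) {
  if (!inherits(config, "simulation_config"))
    abort_config("config must be a simulation_config")
  stream <- (as.numeric(config$seed) * 69091 + as.numeric(subject_seed)) %%
    2147483647
  with_seed(stream, {
    epl <- config$epoch_length_s
    per_h <- 3600 / epl
    psg_n <- as.integer(round(stats::runif(1, config$psg_hours[1],
                                           config$psg_hours[2]) * per_h))
    pad_b <- as.integer(round(stats::runif(1, config$pad_hours[1],
                                           config$pad_hours[2]) * per_h))
    pad_a <- as.integer(round(stats::runif(1, config$pad_hours[1],
                                           config$pad_hours[2]) * per_h))
    n <- pad_b + psg_n + pad_a
    phase <- rep(c("day", "night", "day"), c(pad_b, psg_n, pad_a))

    # Hidden state path: within each phase segment the chain starts from the
    # phase's equilibrium occupancy and alternates with geometric-mixture
    # dwell times.
    state <- integer(n)
    seg_bounds <- c(0L, pad_b, pad_b + psg_n, n)
    for (si in 1:3) {
      from <- seg_bounds[si] + 1L
      to <- seg_bounds[si + 1L]
      if (from > to) next
      ph <- phase[from]
      f <- if (ph == "night") config$night_sleep_fraction
           else config$day_sleep_fraction
      s <- stats::rbinom(1L, 1L, f)
      t <- from
      first <- TRUE
      while (t <= to) {
        d <- .rdwell(.dwell_mean(config, s, ph, stationary = first))
        first <- FALSE
        hi <- min(t + d - 1L, to)
        state[t:hi] <- s
        t <- hi + 1L
        s <- 1L - s
      }
    }

    # Zero-inflated gamma count emissions.
    counts <- numeric(n)
    for (s in c(0L, 1L)) {
      idx <- which(state == s)
      if (!length(idx)) next
      zp <- if (s == 1L) config$sleep_zero_prob else config$wake_zero_prob
      mu <- if (s == 1L) config$sleep_count_mean else config$wake_count_mean
      sh <- if (s == 1L) config$sleep_count_shape else config$wake_count_shape
      nonzero <- stats::rbinom(length(idx), 1L, 1 - zp) == 1L
      counts[idx] <- 0
      counts[idx[nonzero]] <- stats::rgamma(sum(nonzero), shape = sh,
                                            scale = mu / sh)
    }

    psg_stage <- rep(NA_integer_, n)
    inside <- (pad_b + 1L):(pad_b + psg_n)
    psg_stage[inside] <- ifelse(state[inside] == 1L,
                                sample(1:5, psg_n, replace = TRUE), 0L)

    flip <- stats::rbinom(n, 1L, config$annotation_flip_prob)
    annotation <- as.integer(xor(state == 1L, flip == 1L))

    start_time <- as.POSIXct("2000-01-01 21:30:00", tz = "UTC") -
      pad_b * epl
    s <- epoch_series(subject_id, counts, psg_stage = psg_stage,
                      annotation = annotation, epoch_length_s = epl,
                      start_time = start_time)
    s$hidden_state <- state
    s
  })
}

#' Generate a synthetic cohort
#'
#' Subjects are independent, with per-subject seeds derived by a counter
#' scheme from the master seed (subject i uses `subject_seed = i`), so a
#' cohort is stable under subject-count changes up to the shared prefix.
#' Default-configuration cohorts pass [apply_cohort_filters()] with zero
#' exclusions by construction.
#'
#' @param config A [simulation_config()].
#' @return Named list of [epoch_series], length `config$n_subjects`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    abort_config("config must be a simulation_config")
  out <- lapply(seq_len(config$n_subjects), function(i)
    generate_subject(config, i))
  stats::setNames(out, vapply(out, `[[`, character(1), "subject_id"))
}
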