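---
title: "Sleep-wake scoring from actigraphy: models, metrics and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-wake scoring from actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

## The problem

Wrist actigraphy summarizes movement into per-epoch *activity counts*
(30-s epochs here). Scoring each epoch as sleep (1) or wake (0) from those
counts is the core task of actigraphy-based sleep assessment; the gold
standard against which scorers are judged is technician-scored
polysomnography (PSG), whose stages are collapsed to a binary hypnogram
(stages 1–4 and REM map to sleep, stage 0 to wake). From the epoch-level
labels flow the clinically relevant quantities: wake after sleep onset
(WASO, minutes of wake strictly after the first true sleep epoch) and sleep
efficiency (percentage of sleep epochs over the whole record).

`actisleep` packages that benchmark end to end: the six classical
count-threshold scorers, Webster's wake-rescoring rules, sliding-window
features and learned classifiers, the evaluation metrics, two evaluation
tasks (Night: the PSG window only; Night&Day: up to 8 h of day-time wear on
each side, with expert rest annotations as the day truth), and a seeded
synthetic-cohort generator so that every stage is testable without access
to restricted sleep-study data.

## The traditional scorers

All six algorithms reduce to a per-epoch score compared against a cut-off.
Four are weighted sums over a fixed offset window,
$s_t = P \sum_i w_i\, c_{t+i}$, with out-of-range and missing counts
contributing zero:

* **Cole–Kripke**: $D_t = 0.001\,(106\,c_{t-4} + 54\,c_{t-3} + 58\,c_{t-2}
  + 76\,c_{t-1} + 230\,c_t + 74\,c_{t+1} + 67\,c_{t+2})$, sleep iff
  $D_t < 1$.
* **Webster**: scale $0.025$, weights $(.15, .15, .15, .08, .21, .12, .13)$
  over offsets $-4\ldots 2$, sleep iff the score is below 1.
* **Scripps Clinic**: scale $0.204$ with a symmetric 21-coefficient window
  over offsets $-10\ldots 10$ (peak $0.3$ at the center), sleep iff below 1.
* **Oakley** (the Actiwatch device family): weights $1/25$ at $\pm 2$ min,
  $1/5$ at $\pm 1$ min and 1 at the center, *wake* iff the total exceeds a
  threshold $\theta$ ($\theta = 40$ is the device setting; 10 and 80 are
  common alternatives). A score exactly at $\theta$ is scored sleep.

**Sadeh** is a linear model on window statistics,
$PS_t = 7.601 - 0.065\,\mathrm{AVG} - 1.08\,\mathrm{NAT} -
0.056\,\mathrm{SD} - 0.703\,\mathrm{LG}$, with AVG the mean count over
$[t-5, t+5]$, NAT the number of epochs in that window with counts in
$[50, 100)$, SD the standard deviation over $[t-5, t]$ and
$\mathrm{LG} = \ln(c_t + 1)$; sleep iff $PS_t \ge 0$. **Sazonov** is the
one *causal* scorer: $S_t = 1.727 - 0.256\,w_1 - 0.154\,w_2 - 0.136\,w_3 -
0.140\,w_4 - 0.176\,w_5$ where $w_k$ is the maximum count over the trailing
window $[t-k+1, t]$; sleep iff $S_t \ge 0.5$.

Numerical conventions, chosen once and tested: coefficients are applied on
the native 30-s grid without resampling (the Oakley minute-weights are
mapped minute-bin-wise onto half-minute offsets); windows are zero-padded at
the record boundaries; missing counts contribute zero to weighted sums and
are dropped from Sadeh's window denominators; an epoch whose own count is
missing gets a missing prediction; Sadeh's SD term uses the population
(divisor $n$) formula — with constant windows both conventions give 0.
The registry embeds a source note per algorithm, and `score()` accepts
per-call overrides (e.g. Oakley's $\theta$). The coefficient sets are the
canonical published ones; where the benchmark literature leaves room (exact
Oakley/Scripps/Sazonov transcriptions, count transformations), the registry
entry records the convention adopted so users can re-register variants via
`register_scorer()`.

## Rescoring rules

Count-threshold scorers over-call sleep. Webster's five rules flip short
sleep runs near long wake runs back to wake: after wake runs of at least
4/10/15 epochs, the first 1/3/4 sleep epochs are rescored (R1–R3); sleep
islands of at most 6/10 epochs flanked by a wake run of at least 10/20
epochs are rescored entirely (R4–R5). Rules are applied sequentially, one
full pass each.

Two genuinely open readings are pinned down and exposed:

* *Flanking*: "surrounded by at least N epochs (before or after)" is read
  disjunctively — either flank suffices — which is the default; the
  conjunctive reading of Webster's original is available via
  `webster_rules("and")`.
* *Cascading*: within one rule's pass, run lengths are measured on the pass
  input, so a freshly rescored epoch cannot re-trigger the same rule in
  that pass (otherwise R1 alone would erase arbitrarily long sleep blocks);
  cascading *between* passes is preserved. Repeated application converges
  to a fixed point, but idempotence after one application is deliberately
  not claimed.

Missing labels break runs and are never rescored. Because only
sleep-to-wake changes occur, rescoring can never raise sensitivity or lower
specificity — both are property-tested, and the whole interpreter is checked
exhaustively against an independent brute-force implementation on all 4096
binary strings of length 12.

## Features and learned classifiers

The classical classifiers consume a deterministic 370-column feature matrix
per epoch: the raw count and $\ln(c_t+1)$, plus summary statistics of
centered ($[t-N, t+N]$) and trailing ($[t-N, t]$) windows for
$N = 1\ldots 19$. Windows of $N \ge 2$ carry ten statistics (mean, median,
SD, variance, min, max, sum, range, IQR, nonzero proportion); the smallest
windows ($N = 1$, i.e. 2–3 values) carry only mean, min, max and sum, since
spread and quantile statistics are near-degenerate there. That composition
— $2 + 36 \times 10 + 2 \times 4 = 370$ — is the package's documented
default; it is one concrete realization of the published feature-count
contract, and alternative compositions can be supplied as a
`feature_schema`. Boundaries are zero-filled by default (an actigraph
reports 0 for no movement); a truncate policy is available.

Four classical models (ridge-penalized logistic regression via `glmnet`,
linear SVM via `e1071`, an averaged perceptron, extremely randomized trees
via `ranger`) and two small sequence models (a 1-D CNN and an LSTM on
fixed-width raw-count windows of 20/50/100 epochs, zero-padded and centered
on the target epoch) share one training protocol: grid search by k-fold
cross-validation (5 folds by default) maximizing accuracy, winner refit on
all data, reproducible from the seed. Folds are formed at the subject level
when subject ids are supplied — the default protocol, avoiding
within-subject leakage — with contiguous epoch blocks otherwise.

The sequence models are intentionally small reference stacks written
natively in R (one convolution + ReLU + mean-pool + logistic readout; one
LSTM layer + logistic readout on the final hidden state), trained
full-batch with Adam on binary cross-entropy. Their analytic gradients are
verified against finite differences in the test suite. They document the
pipeline contract for window-input models; they are not tuned for
leaderboard parity.

## Metrics and the benchmark harness

Sleep is the positive class: sensitivity is the fraction of true sleep
detected, specificity the fraction of true wake detected. Any metric with a
zero denominator is defined as 0, which reproduces the conventional
always-wake row (precision, sensitivity and F1 all 0). WASO counts
predicted wake strictly after the true onset epoch; the onset epoch itself
is excluded. Sleep efficiency uses the entire record of non-missing
predictions, so an always-sleep predictor scores WASO 0 and efficiency 100
regardless of the truth.

Cohort reporting is *per-subject-then-average*: every metric is computed
per subject and summarized as mean ± 1.96·SD/√n (a normal-approximation 95%
interval — the CI convention is a documented package choice). Mean absolute
errors of WASO and sleep efficiency against the ground truth, and a
ground-truth oracle row exposing the cohort's true WASO/efficiency, are
reported for the night task only. Methods are compared against the four
baselines (always-sleep, always-wake, the device algorithm — Oakley with
$\theta = 40$ — and the expert manual annotation) with paired two-tailed
t-tests on per-subject accuracy and F1; identical paired samples return
p = 1 by convention, a constant nonzero difference p = 0.
`metric_correlations()` computes the Pearson matrix across method rows; the
packaged 41-row published night-task table reproduces the reported
correlations r(F1, MAE WASO) = −0.98 and r(accuracy, MAE sleep efficiency)
= −0.93 to two decimals.

## The synthetic cohort

The generator emulates the structure of a large PSG-synchronized actigraphy
cohort; its defaults are the study conditions, not tuning knobs:

* **Timeline** — a PSG night of U(9, 12) h (mean 10.5 h, matching the
  published cohort's ≈10.4 h of PSG per subject) flanked by U(4, 8) h of
  day wear on each side; generated records always pass the cohort filters.
* **Sleep architecture** — a two-state semi-Markov chain with
  geometric-mixture dwell times, so consolidated sleep bouts (mean 90
  epochs, 30% short bouts of mean 20) coexist with brief awakenings (75%
  of night wake bouts have mean 4 epochs) and long lights-on wake. The
  night stationary sleep fraction is configured at 0.584, the published
  cohort's night sleep share; day phases use a 6% nap fraction with
  15-min mean naps, which puts the night-and-day wake share near the
  published ≈69%. The first bout of each phase segment draws its mixture
  component with length-biased weights — the stationary residual law for
  geometric mixtures — so the realized sleep fraction is unbiased for the
  configured one (verified within ±3 pp over 200 subjects).
* **Emissions** — zero-inflated gamma counts: sleep epochs are 85% zeros
  with nonzero mean 5 (shape 0.7); wake epochs are 30% zeros with nonzero
  mean 150 (shape 1.0). Monte-Carlo recovery of these means is tested at
  >10⁵ epochs.
* **Annotation** — the simulated expert channel equals the hidden state
  with a 2% per-epoch flip, consistent with the >90% inter-scorer
  reliability reported for expert rest annotation. Because the
  night-and-day task takes the annotation as day truth, this flip rate is
  part of the task definition.
* **Stages** — hidden sleep states get stage codes 1–5 uniformly; nothing
  downstream uses stage identity beyond the binary collapse, so no
  stage-sequencing realism is attempted.

Per-subject seeds derive from the master seed by a counter scheme
(`seed * 69091 + i`), so cohorts are stable under subject-count changes up
to the shared prefix.

What the simulator does *not* emulate: device-specific count generation,
circadian structure beyond the two-phase night/day switch, disease
phenotypes (insomnia, apnea, movement disorders), off-wrist gaps. Passing
tests on synthetic cohorts therefore demonstrate pipeline correctness and
the documented statistical contracts — not clinical performance on real
populations, whose absolute accuracies require the restricted source
cohort and full-scale training.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
synthetic cohorts of 150–200 subjects (≈2·10⁵–4·10⁵ epochs) for the
calibration checks, 3–40 subjects for harness behavior, windows ≤ 100 and
a few hundred epochs for the sequence models. All randomness flows through
explicit integer seeds; `with_seed()` isolates the package's draws from the
caller's RNG state.

## Known limitations

* The 370-column schema is one documented composition consistent with the
  published feature count; the exact original composition is not public.
* The Oakley/Scripps/Sazonov coefficient transcriptions follow the
  canonical published algorithm descriptions; registry entries carry their
  source notes so any variant can be swapped in.
* Night-and-day truth treats annotated rest outside PSG as sleep (the nap
  rule); whether rest intervals equal sleep intervals in expert practice is
  an open semantic question, and the annotation channel is exposed so users
  can apply their own mapping.
* The CNN/LSTM reference stacks are single-layer and full-batch; they are
  contracts, not competitive architectures.
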