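# actisleep

Epoch-by-epoch sleep-wake scoring for wrist actigraphy, benchmarked against
polysomnography (PSG).

Actigraphy devices summarize movement into per-epoch **activity counts**
(30-s epochs). Deciding whether each epoch is sleep (1) or wake (0) from
those counts is the core task of actigraphy-based sleep assessment, and the
choice of scoring algorithm materially changes the clinical read-out: wake
after sleep onset (WASO) and sleep efficiency. `actisleep` implements the
standard benchmark for this task end to end:

* **Traditional scorers** — Webster, Cole–Kripke, Sadeh, Oakley (the
  Actiwatch device algorithm at θ = 40, with θ = 10/80 variants), Sazonov
  (the one causal scorer) and Scripps Clinic, as parameterized epoch
  scorers over a coefficient registry. E.g. Cole–Kripke scores
  `D_t = 0.001·(106 c_{t−4} + 54 c_{t−3} + 58 c_{t−2} + 76 c_{t−1} +
  230 c_t + 74 c_{t+1} + 67 c_{t+2})`, sleep iff `D_t < 1`.
* **Webster's five rescoring rules** (R1–R5), applied sequentially, with the
  either-flank / both-flanks ambiguity exposed as a switch.
* **Features and classifiers** — a deterministic 370-column sliding-window
  feature matrix; logistic regression, linear SVM, averaged perceptron and
  extra trees on features; small native CNN/LSTM reference stacks on raw
  count windows (20/50/100 epochs); 5-fold CV grid search maximizing
  accuracy, subject-level folds by default.
* **Metrics** — accuracy/sensitivity/specificity/precision/F1 with sleep as
  the positive class, WASO (minutes of predicted wake strictly after the
  true onset), sleep efficiency, per-subject-then-average cohort summaries
  (mean ± 1.96·SD/√n), MAE against ground truth, paired two-tailed t-tests,
  and metric–metric Pearson correlations.
* **Tasks and harness** — Task Night (PSG window, PSG truth) and Task
  Night&Day (up to 8 h of day wear each side, expert rest annotation as day
  truth, naps scored sleep); four baselines (always-sleep, always-wake,
  device algorithm, manual annotation) plus a ground-truth oracle row.
* **Synthetic cohorts** — a seeded two-state semi-Markov simulator
  (geometric-mixture bouts, zero-inflated gamma count emissions, noisy
  expert channel) calibrated to the published cohort composition (58.4%
  night sleep, ≈69% night&day wake, ≈10.5 h PSG), so the full pipeline runs
  without restricted data. Cohort exclusion filters (<3 h usable overlap,
  >16 h PSG) and the 80/20 subject split round out the data layer. The MESA
  Sleep overlap-file layout is supported as an input dialect, but no
  restricted data is required or included.

See `vignettes/actigraphy-benchmark.Rmd` for the models, conventions and
design decisions in full.

## Worked example

```r
library(actisleep)

cfg    <- simulation_config(n_subjects = 8, seed = 2026)
cohort <- generate_cohort(cfg)           # 8 synthetic subjects
night  <- build_task(cohort, "night")    # PSG-window task with PSG truth

bm <- run_benchmark(night, methods = c("cole_kripke", "sadeh", "oakley"),
                    rescore = TRUE)
print(bm)
```

```
<benchmark_result> task night, 8 subjects, 11 rows
            method    group accuracy_mean f1_mean waso_mean mae_waso
      Ground truth   oracle         100.0   100.0       183     0.00
 Manual annotation baseline          97.7    98.1       190     7.06
  Device algorithm baseline          96.6    97.2       177     6.19
      Always sleep baseline          68.5    79.7         0   183.12
       Always wake baseline          31.5     0.0       626   442.94
            oakley   method          96.6    97.2       177     6.19
             sadeh   method          96.4    97.0       176     7.88
       cole_kripke   method          86.0    88.7       272    89.25
      Resc. oakley rescored          96.3    96.6       202    19.06
       Resc. sadeh rescored          96.0    96.4       200    16.44
 Resc. cole_kripke rescored          78.6    81.1       321   137.88
 ...
```

Reading the output: the always-sleep row's accuracy (68.5) is the cohort's
night sleep fraction — the floor any useful scorer must beat. The oracle row
exposes the true cohort WASO (183 min here) and sleep efficiency; each
method's `mae_waso` / `mae_sleep_eff` measure how far its clinical read-out
sits from that truth, per subject. The device baseline row is identical to
the `oakley` method row by construction (θ = 40 *is* the device algorithm).
Rescored variants trade sensitivity for specificity: WASO rises, sleep
efficiency falls.

Paired significance against any baseline comes with the result:

```r
round(bm$significance$accuracy[, "Device algorithm"], 4)
#>       cole_kripke Resc. cole_kripke             sadeh       Resc. sadeh
#>            0.0010            0.0002            0.2591            0.4160
#>            oakley      Resc. oakley
#>            1.0000            0.5541
```

Single-subject scoring is one call:

```r
score("cole_kripke", cohort[[1]]$counts)
#> <score_series> cole_kripke: 2783 epochs, 26.7% scored sleep
```

A thin command-line front-end (`inst/cli/actisleep`) wraps the same
functions: `simulate`, `score --algorithm oakley --theta 40`, `rescore
--flank-mode or`, and `benchmark --task night --rescore`, with exit codes
distinguishing validation (2) from configuration (3) errors.

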