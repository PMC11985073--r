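# jellyfeed

Quantitative ethology of a stereotyped cnidarian feeding sequence, and
how satiety takes it apart.

Jellyfish such as *Cladonema* feed through an ordered chain of clearly
distinguishable steps — prey **contact** (t = 0), **paralysis**, the
**tentacle contraction reflex** (TCR), tentacle **bending**, and
**ingestion** — observed per prey offer within a 2-minute window per
step. After a meal the animal enters satiety: transitions between steps
become less likely and step onsets are delayed, while the motor programs
themselves (step durations) stay intact. `jellyfeed` is the analysis
toolkit for this kind of data: it parses annotated behavioral event
tables, enforces the sequence grammar, and quantifies the sequence and
its timing under different feeding states.

For behavioral ecologists and neuroethologists, the package provides:

* **Ethogram I/O** — a validated long CSV dialect (one row per behavioral
  event), with a parse report that rejects and documents
  grammar-violating annotations; round-trip safe.
* **Sequence statistics** — first-order transition tables
  P(next behavior | step), agreement probabilities between each
  tentacle-mediated step and ingestion, and per-animal prey consumption.
* **Censored timing analysis** — Kaplan-Meier cumulative fractions
  1 − S(t) per step, percentile times T25/T50/T75 read from the curve
  without interpolation, T50 fold changes between conditions, log-rank
  (Mantel-Cox) tests, and adjacent-step timing correlations.
* **A nonparametric test battery** — Fisher's exact (probability-mass
  two-sided rule), Pearson chi-square, Mann-Whitney (exact for small
  untied samples), Kruskal-Wallis with Dunn's posttest, and Bonferroni
  correction with explicit family sizes.
* **A semi-Markov behavior generator** — seeded, bit-reproducible
  synthetic prey-offer episodes with per-step success probabilities π_s
  and log-normal latency/duration draws, plus presets for every study
  arm (starved/fed animals, used/unused tentacles, manubrium-less
  animals, severed tentacles, and a post-meal satiety time course).

## Worked example

```r
library(jellyfeed)

starved <- simulate_dataset("starved", seed = 1)   # 19 animals x 5 offers
fed     <- simulate_dataset("fed", seed = 1001)    # 18 animals x 5 offers

tt <- transition_matrix(starved$observations, "paralyze")
tt
#> <transition_table> from paralyze (n = 87, 8 excluded)
#>    tcr   bend ingest   none
#>  0.954  0.000  0.000  0.046

agreement_probability(starved$observations, "tcr")
#> <agreement_result> tcr vs ingestion: 0.905 (86/95)

tim_s <- extract_timings_all(starved$observations)
tim_f <- extract_timings_all(fed$observations)
t50_fold_change(latency_sample(tim_f, "tcr"), latency_sample(tim_s, "tcr"))
#> $ratio
#> [1] 7.118441
#> $t50_num
#> [1] 29.85625
#> $t50_den
#> [1] 4.194424
```

Read: in starved animals 95% of paralyzed prey progress to the TCR and
TCR occurrence agrees with eventual ingestion in 90% of offers; feeding
shifts the median TCR onset from ~4 s to ~30 s — a 7.1-fold delay in this
simulated cohort, recovering the generator's built-in satiety effect.

The numbered scripts under `analysis/` run the whole study workflow —
`01_simulate.R` (all condition arms at study-scale n), `02_sequence_stats.R`
(transitions, agreement, consumption), `03_latency_stats.R` (KM curves,
fold changes, duration tests, correlations), `04_time_course.R` (satiety
dynamics in isolated tentacles) — writing tables and figures under
`results/`. The time-course output shows the signature dissociation: TCR
inhibition is already significant 5 minutes after a meal, the paralysis
delay only at 60 minutes.

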