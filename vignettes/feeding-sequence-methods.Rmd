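---
title: "Methods: quantifying a stereotyped feeding sequence under satiety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a stereotyped feeding sequence under satiety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellyfeed)
```

## The behavioral model

`jellyfeed` analyzes prey-offer episodes in cnidarians whose feeding is a
stereotyped, ordered sequence of five steps: **contact** (prey touches an
outstretched tentacle, defining t = 0), **paralyze** (nematocyte-mediated
prey paralysis, annotated by its completion time point), **tcr** (the
tentacle contraction reflex that retrieves the prey), **bend** (the
contracted tentacle bends under the umbrella), and **ingest** (the
manubrium takes the prey). The package's sequence grammar is
*strict-prefix*: a step of rank r can only be scored if every earlier step
occurred. Annotated tables violating the grammar are rejected with a
reason and preserved in the parse report for audit, never silently
reordered — deviant sequences are a data-quality question, not something
an analysis should repair on the fly.

Each prey offer is one `observation`. Two quantities describe each
executed step:

* **latency** — for paralyze, the time from contact to paralysis
  completion (conventionally called the paralyze *duration*, t1, because
  the annotation is the completion time point); for later steps, the
  inter-step interval (ISI) from the preceding step's offset to this
  step's onset;
* **duration** — offset minus onset, defined for tcr, bend and ingest.

A step not executed within `window_s` seconds (default 120) of its timing
reference is **right-censored** at the window. We read the 2-minute
observation period as *per step*, measured from each step's own timing
reference, not as 120 s for the whole sequence: a complete feeding bout
typically takes 2–3 minutes, which would be impossible under a global
2-minute horizon. `window_s` is configurable for datasets scored
differently.

## Sequence statistics

`transition_matrix()` counts, for observations that executed a given step,
the next canonical step executed afterwards (or `"none"`). Skip-ahead
outcomes (e.g. paralyze → bend without a TCR) keep their own columns;
collapsing to "canonical next vs anything else" happens only when a 2×2
table is needed for Fisher's exact test (`transition_2x2()`), which is the
minimal faithful reduction for comparing the dominant transition between
conditions; the full r×c table remains available for chi-square
comparisons. Probabilities below a configurable threshold (default 0.05,
strictly below) are merely *rendered* de-emphasized in heatmaps — the
threshold never filters data.

`agreement_probability()` scores, per observation, whether a
tentacle-mediated step and ingestion both occurred or both failed within
the window; censored observations count as failures because occurrence is
defined within the observation period. `consumption_counts()` aggregates
ingestion successes per subject over its sequential offers (5 per animal
in the intact-animal protocol).

## Censored timing analysis

`km_curve()` is the product-limit estimator reported as a cumulative
fraction 1 − S(t). Because never-responders are censored at the window,
curves may plateau below 1. Percentile times T25/T50/T75 are read off the
step function as the *first event time* at which the cumulative fraction
reaches the target — no interpolation, matching the estimator's step
nature. A percentile the curve never reaches is "not reached" and any
fold change involving it is explicitly undefined (never infinity).

A step's latency clock starts only when its timing reference exists, so
each step's Kaplan-Meier sample conditions on the preceding step having
been executed; this is why per-step sample sizes shrink along the
sequence. Ties are handled the standard way (events before censorings at
a tied time).

Two conventions coexist deliberately: percentile boxes (T25/T50/T75) come
from the KM curve, which respects censoring, while Mann-Whitney
comparisons use the *uncensored values only* — censored times are not
exchangeable ranks, and `mann_whitney()` refuses flagged censored input.
Group comparisons of the full censored samples use the log-rank
(Mantel-Cox) test (`logrank_test()`, two-group or k-group). All tests are
two-sided.

`adjacent_timing_correlation()` (Spearman, on observations where both
quantities are uncensored) checks whether the timings of adjacent steps
covary; independence supports separately controlled steps.

## The test battery

Standard machinery is delegated to base R and `survival`; the package
fixes the conventions:

* Fisher's exact test, two-sided by the probability-mass rule (sum of all
  margin-fixed tables no more probable than the observed one). The
  doubling rule is a known alternative; the probability-mass rule is what
  this package uses, and tests verify it against full hypergeometric
  enumeration.
* Pearson chi-square without continuity correction, with a warning when
  expected counts fall below 5 and an error on zero margins.
* Mann-Whitney: exact permutation p when the smaller sample has ≤ 8
  untied values (enumeration is cheap there), otherwise the normal
  approximation with tie and continuity corrections.
* Kruskal-Wallis with tie correction; Dunn's z on mean ranks as the post
  hoc, adjusted by Bonferroni over the pairs actually tested —
  configurable between all pairs and versus-control, since post hoc
  software differs in which family it corrects over. The time-course
  analysis uses versus-control (each post-meal arm against the starved
  control), matching how the arms are compared.
* `bonferroni()` takes an explicit family size m ≥ the number of p-values
  supplied, because a figure's family can include tests not passed into
  one call.

## The synthetic-behavior generator

`simulate_observation()` walks the canonical sequence as a semi-Markov
chain: given the predecessor occurred, step s occurs with probability
π_s, its latency is drawn log-normal(median m_s, log-scale σ_s), and a
draw beyond the window — or a failed success draw — terminates the
sequence. Executed tcr/bend/ingest steps draw independent log-normal
durations. Censoring is therefore *emergent* (slow responders) plus
*explicit* (never-responders), which is what produces plateauing
cumulative-fraction curves of the observed shape.

Distribution choices: latencies are log-normal for positive support and a
heavy right tail consistent with the observed curves; the study reports
no distributional form, so the family is a modeling choice (the config
interface would accept any positive family). The log-scales are fixed
once at σ = 0.5 for latencies (giving an interquartile ratio of about 2,
consistent with the reported box spreads) and 0.4 for durations.

The preset library encodes the study arms with their reported sample
sizes (19/18 intact animals × 5 offers; 79/69 used/unused-tentacle
offers; severed-tentacle arms with one offer per well; time-course arms
of 87/62/74/67/64 tentacles). Satiety is modeled as *lower π and longer
latency medians with unchanged durations* — the fed TCR ISI median is 5×
the starved one (the largest reported effect), paralysis and bend about
2×, ingestion 2.5×. The time-course presets encode the dissociation as
generator truth: the TCR multiplier is 5× from 5 min post-meal onward,
while the paralysis multiplier is 1× at 5–30 min and 2× only at 60 min.
The pipeline must *rediscover* these facts from simulated event tables;
none of the analysis code sees the truth record.

Reproducibility: each subject draws from a deterministic sub-stream of
the dataset seed, so identical (config, seed) regenerate event tables
byte-for-byte, and single subjects can be regenerated without replaying
the whole dataset.

### What the generator does and does not emulate

It emulates the sequence grammar, condition-dependent success
probabilities, latency scales, per-step censoring, and repeated offers
per animal. It does not emulate annotation noise or jitter, within-animal
correlation beyond shared parameters (offers are conditionally
independent given the arm), prey behavior, or any mechanistic biology
(nematocyte discharge, neuropeptide signaling). Tests passing on
synthetic data therefore certify the *statistical pipeline* — not claims
about real animals, for which the deposited raw data remain the
reference (`validate_deposit()` accepts a local export of the public
deposit).

## Verification design

Every exact statistic has an independent brute-force oracle in the test
suite: full hypergeometric enumeration for Fisher (all 2×2 tables with
grand total ≤ 40), complete permutation enumeration for small-sample
Mann-Whitney, a hand-written product-limit computation for KM (and the
empirical CDF in the censoring-free case), and a hand observed-vs-expected
tabulation for the log-rank statistic.

Simulation-based checks run at deliberately chosen scales: 2000 null
replicates at 50 observations per arm verify each test's size lands in
[0.03, 0.07] at α = 0.05 (the exact test is conservative by
construction); 200 replicates at 100 per arm verify the T50 fold-change
estimator recovers a generator truth of 5 within [4, 6] at least 90% of
the time; 200 replicates at study-scale arm sizes verify the time-course
dissociation (TCR significant at 5 min, paralysis only at 60 min) in at
least 80% of replicates. The fold-recovery experiment fixes transition
success at 1 so the latency fold is the only truth being recovered —
transition-probability recovery is checked separately at n = 500 against
π·P(latency ≤ window), within 3 binomial standard errors.

## Numerical and degenerate-input conventions

* All-censored samples give a flat curve at 0 with a warning, not an
  error; percentiles are "not reached".
* A log-rank call with zero events in every group returns statistic 0,
  p 1, with a warning.
* Zero-variance (σ = 0) generator distributions are honored exactly,
  giving deterministic sequences — useful for fixtures.
* Transition tables refuse an empty denominator (no observation executed
  the from-step).
* Probabilities are validated to row-normalize within 1e-12.

## A worked example

```{r example, eval = FALSE}
starved <- simulate_dataset("starved", seed = 1)
fed <- simulate_dataset("fed", seed = 1001)
tim_s <- extract_timings_all(starved$observations)
tim_f <- extract_timings_all(fed$observations)
t50_fold_change(latency_sample(tim_f, "tcr"), latency_sample(tim_s, "tcr"))
```

The numbered scripts under `analysis/` run this workflow end to end
(simulate → sequence statistics → timing analysis → time course) and
write their tables under `results/`.

## Known limitations

* The pipeline starts from annotated event tables; it does not detect
  events in video.
* First-order transitions only; the sequence is modeled without
  multi-step memory, which matches a strictly ordered ethogram but would
  not capture higher-order structure.
* Exact r×c Fisher tests (Freeman-Halton) are out of scope; r×c tables
  go to chi-square.
* p-values are not bit-identical to any particular commercial statistics
  package; tie and continuity conventions are documented above instead.
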