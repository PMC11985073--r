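Package: jellyfeed
Title: Quantitative Ethology of Stereotyped Jellyfish Feeding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of stereotyped, sequential
    feeding behavior in cnidarians, built around annotated behavioral event
    tables. Provides a validated long-format ethogram data model
    (contact, paralyze, tentacle contraction reflex, bend, ingest),
    first-order transition-probability tables, agreement probabilities
    between tentacle-mediated steps and ingestion, prey-consumption counts,
    right-censored latency analysis (Kaplan-Meier cumulative fractions,
    T25/T50/T75 percentile times, median fold changes, log-rank tests),
    a nonparametric test battery (Fisher's exact, chi-square, Mann-Whitney,
    Kruskal-Wallis with Dunn's post hoc, Bonferroni correction), and a
    seeded semi-Markov generator of synthetic feeding observations with
    presets emulating starved/fed animals, tentacle preparations, and
    post-meal satiety time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
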