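#!/usr/bin/env Rscript
# Step 2: feeding-sequence structure in starved vs fed animals.
#
# Transition-probability tables per from-step, agreement between each
# tentacle-mediated step and ingestion, and prey consumption per animal,
# with Fisher's exact comparisons (Bonferroni over the four from-steps)
# and a Mann-Whitney test on consumption. Reads the event tables written
# by 01_simulate.R; writes tidy tables to results/.

suppressPackageStartupMessages(library(jellyfeed))
dir.create("results", showWarnings = FALSE)

arms <- lapply(c(starved = "starved", fed = "fed"), function(p) {
  parse_event_table(
    readr::read_csv(file.path("results/data", paste0(p, ".csv")),
                    show_col_types = FALSE))$observations
})

from_steps <- feeding_steps()[-5]
tabs <- lapply(arms, function(obs) {
  stats::setNames(lapply(from_steps, transition_matrix,
                         observations = obs), from_steps)
})
tidy <- dplyr::bind_rows(
  transition_tidy(tabs$starved) |> dplyr::mutate(condition = "starved"),
  transition_tidy(tabs$fed) |> dplyr::mutate(condition = "fed"))
readr::write_csv(tidy, "results/transitions_starved_fed.csv")

fisher_p <- vapply(from_steps, function(fs) {
  fisher_exact_2x2(transition_2x2(tabs$starved[[fs]], tabs$fed[[fs]],
                                  labels = c("starved", "fed")))$p_two_sided
}, numeric(1))
trans_tests <- tibble::tibble(from_step = from_steps, p = fisher_p,
                              p_adj = bonferroni(fisher_p))
readr::write_csv(trans_tests, "results/transition_tests.csv")
cat("Dominant-transition comparisons (Fisher, Bonferroni m = 4):\n")
print(as.data.frame(trans_tests), digits = 3)

agree <- dplyr::bind_rows(lapply(names(arms), function(a) {
  dplyr::bind_rows(lapply(c("paralyze", "tcr", "bend"), function(st) {
    g <- agreement_probability(arms[[a]], st)
    tibble::tibble(condition = a, step = st, n = g$n,
                   probability = g$probability)
  }))
}))
readr::write_csv(agree, "results/agreement.csv")
cat("\nAgreement with ingestion (fraction concordant):\n")
print(as.data.frame(agree), digits = 3)

cons <- consumption_counts(c(arms$starved, arms$fed))
cons_sum <- consumption_summary(cons)
mw <- mann_whitney(cons$consumed[cons$feeding_state == "starved"],
                   cons$consumed[cons$feeding_state == "fed"])
readr::write_csv(cons_sum, "results/consumption_summary.csv")
cat(sprintf("\nConsumption: starved %.2f vs fed %.2f of 5 shrimp (Mann-Whitney p = %.2g)\n",
            cons_sum$mean_consumed[cons_sum$feeding_state == "starved"],
            cons_sum$mean_consumed[cons_sum$feeding_state == "fed"],
            mw$p_two_sided))
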