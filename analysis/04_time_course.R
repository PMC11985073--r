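#!/usr/bin/env Rscript
# Step 4: satiety dynamics in isolated tentacles.
#
# Severed-tentacle arms measured 5/10/30/60 min after a brief meal against
# a starved control: chi-square comparison of the dominant transition,
# multi-group log-rank over the latency curves, and Kruskal-Wallis with
# Dunn's posttest (vs control, Bonferroni) on the uncensored paralysis
# times and TCR ISIs. The signature result this reproduces: TCR inhibition
# is already present at 5 min, the paralysis delay only at 60 min.

suppressPackageStartupMessages(library(jellyfeed))
dir.create("results", showWarnings = FALSE)

presets <- c("tc_starved", "fed_tc_5", "fed_tc_10", "fed_tc_30", "fed_tc_60")
obs <- lapply(stats::setNames(presets, presets), function(p) {
  parse_event_table(
    readr::read_csv(file.path("results/data", paste0(p, ".csv")),
                    show_col_types = FALSE))$observations
})
tim <- lapply(obs, extract_timings_all)

# dominant paralyze -> TCR transition across arms (2 x k chi-square)
tabs <- lapply(obs, transition_matrix, from_step = "paralyze")
m <- t(vapply(tabs, function(tt) {
  k <- tt$counts[tt$outcomes == "tcr"]
  c(tcr = k, other = tt$n - k)
}, numeric(2)))
chi <- chi_square_test(m)
cat(sprintf("Paralyze->TCR transition across arms: chi-square %.2f (df %d), p = %.2g\n",
            chi$statistic, chi$df, chi$p))

out <- list()
for (st in c("paralyze", "tcr")) {
  samples <- lapply(tim, latency_sample, step = st)
  lr <- logrank_test(samples)
  g <- lapply(samples, function(s) s$times_s[s$observed])
  kw <- kruskal_wallis_dunn(g, pairs = "control")
  pw <- kw$pairwise
  pw$step <- st
  out[[st]] <- pw
  cat(sprintf("\n%s: multi-group log-rank chi-square %.1f (df %d, p = %.2g); Kruskal-Wallis H %.1f (p = %.2g)\n",
              st, lr$chi_square, lr$df, lr$p_two_sided, kw$H, kw$p_overall))
  cat("Dunn vs starved control (Bonferroni-adjusted):\n")
  print(as.data.frame(pw[, c("group2", "z", "p_adj")]), digits = 3)
}
readr::write_csv(dplyr::bind_rows(out), "results/timecourse_dunn.csv")

p_par <- out$paralyze$p_adj
p_tcr <- out$tcr$p_adj
cat(sprintf("\nDissociation: TCR prolonged at 5 min (p_adj = %.2g) while paralysis reaches significance only at 60 min (5-30 min all p_adj >= 0.05: %s; 60 min p_adj = %.2g)\n",
            p_tcr[1], all(p_par[1:3] >= 0.05), p_par[4]))
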