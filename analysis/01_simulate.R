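#!/usr/bin/env Rscript
# Step 1: generate the synthetic study arms.
#
# Simulates every condition preset at its study-scale sample size and
# writes the event tables (long CSV dialect) plus the generator truth to
# results/data/. Downstream scripts start from these files, exactly as the
# analysis of annotated videos would start from exported event tables.

suppressPackageStartupMessages(library(jellyfeed))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

presets <- names(preset_library())
truths <- list()
for (i in seq_along(presets)) {
  p <- presets[i]
  d <- simulate_dataset(p, seed = seed + i)
  write_event_table(d$observations, file.path(out, paste0(p, ".csv")))
  truths[[p]] <- d$truth
  cat(sprintf("%-28s %4d observations (%d subjects x %d offers)\n",
              p, length(d$observations), d$truth$n_subjects,
              d$truth$offers_per_subject))
}
jsonlite::write_json(truths, file.path(out, "generator_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Event tables and generator truth written to", out, "\n")
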