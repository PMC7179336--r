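#!/usr/bin/env Rscript
# Stage 1 — simulate the demo cohort.
#
# Generates a five-group synthetic EEG cohort (control, schizophrenia, mTBI,
# stroke, coma) with the bundled demo specification: eyes-closed rest plus
# two emotional sound conditions, six subjects per group, the full
# 19-channel montage at 250 Hz. Writes one EDF + events table per subject,
# the ratings table and a checksum manifest under results/cohort/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(nleeg))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260101L

spec_path <- system.file("extdata", "demo_cohort.yaml", package = "nleeg")
spec_yaml <- yaml::read_yaml(spec_path)
spec_yaml$seed <- seed
tmp <- tempfile(fileext = ".yaml")
yaml::write_yaml(spec_yaml, tmp)

man <- run_simulate(tmp, "results/cohort")
cat("Simulated", sum(grepl("\\.edf$", names(man$files))), "recordings",
    "(seed", seed, ") into results/cohort/\n")
cat("Cohort spec hash:", man$config_hash, "\n")
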