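#!/usr/bin/env Rscript
# Stage 3 — group statistics and correlation maps.
#
# Between-group one-way ANOVA per (feature, channel) on eyes-closed rest
# with Bonferroni adjustment over the 19-channel family and Tukey HSD
# post-hocs; stimulation-vs-rest paired contrasts per group and condition;
# the PSD-feature Pearson correlation map masked at p < 0.05, |r| > 0.35;
# and rating-feature correlations for the groups that give ratings.
# Writes TSV reports + a JSON summary under results/stats/.

suppressMessages(library(nleeg))

config <- read_run_config(system.file("extdata", "default_config.yaml",
                                      package = "nleeg"))
reports <- run_stats("results/features", "results/stats", config = config,
                     ratings_path = "results/cohort/ratings.tsv")

cat("Resting group effects (significant channels per feature):\n")
for (f in names(reports$channel_lists))
  cat(sprintf("  %-18s %s\n", f, reports$channel_lists[[f]]))

cm <- reports$psd_correlations
cat("\nSignificant PSD-feature correlations (|r| > 0.35, p < 0.05):",
    sum(cm$significant), "of", nrow(cm), "cells\n")
sig <- cm[cm$significant, ]
if (nrow(sig) > 0) {
  sig$range <- sprintf("%d-%d Hz", sig$bin_lo, sig$bin_hi)
  print(sig[order(sig$feature, sig$bin_lo),
            c("feature", "range", "r", "p")], row.names = FALSE)
}

feats <- read_feature_table("results/features/features.tsv")
stims <- setdiff(unique(feats$condition), c("rest_closed", "rest_open"))
for (g in unique(feats$group)) for (cond in stims) {
  sv <- stim_vs_rest(feats, g, cond, alpha = config$stats$alpha)
  sig <- sv[sv$significant, ]
  if (nrow(sig) > 0)
    cat(sprintf("\n%s / %s: %d significant stim-vs-rest cells (signs: %s)\n",
                g, cond, nrow(sig),
                paste(names(table(sig$sign)), table(sig$sign),
                      sep = ":", collapse = " ")))
}

if (!is.null(reports$rating_correlations)) {
  rc <- reports$rating_correlations
  rc_sig <- rc[rc$significant, ]
  cat("\nSignificant rating-feature correlations:", nrow(rc_sig), "\n")
  if (nrow(rc_sig) > 0)
    print(rc_sig[c("group", "condition", "scale", "feature", "r")],
          row.names = FALSE)
}
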