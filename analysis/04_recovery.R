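#!/usr/bin/env Rscript
# Parameter recovery: (a) two-sample MR of a planted mediated log hazard
# of 0.3 per unit average region methylation (panel n = 2000, cohort
# n = 1000, 200 replicates) -- median IVW estimate and empirical 95% CI
# coverage; (b) recovery of a planted DMR at a 0.05-beta smoking shift
# in cohorts of 409 (100 replicates).  Writes results/recovery.tsv.

suppressMessages(library(ewasmr))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 11L

rec <- experiment_mr_recovery(seed, n_rep = 200, truth = 0.3)
dmr <- experiment_dmr_recovery(seed, n_rep = 100, shift = 0.05)

tab <- data.frame(
  quantity = c("mr_median_loghr", "mr_ci95_coverage", "dmr_recovery_rate"),
  value = c(rec$median_beta, rec$coverage, dmr$recovery_rate),
  truth = c(rec$truth, 0.95, NA),
  n_rep = c(rec$n, rec$n, dmr$n))

dir.create("results", showWarnings = FALSE)
write.table(tab, file.path("results", "recovery.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf("median IVW log-HR %.3f (truth 0.3, relative error %.1f%%)\n",
            rec$median_beta, 100 * abs(rec$median_beta - 0.3) / 0.3))
cat("wrote results/recovery.tsv\n")
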