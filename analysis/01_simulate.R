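#!/usr/bin/env Rscript
# Simulate the synthetic study: a reference mQTL panel and a clinical
# cohort of oropharyngeal-cancer cases with a planted mediated effect of
# regional methylation on survival.  Writes the cohort-side inputs under
# results/data/ and reports the realized study conditions.

suppressMessages(library(ewasmr))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 11L

cfg <- sim_config(seed = seed)
panel <- simulate_reference_panel(cfg)
cohort <- simulate_clinical_cohort(cfg, panel$truth)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ph <- cohort$phenotypes
ph$survival_days <- cohort$survival_days
ph$event <- cohort$event
write_stage_table(ph, file.path(out, "phenotypes.tsv"), "phenotype")
write_matrix_tsv(cohort$methylation$beta,
                 file.path(out, "methylation.tsv"), c(0, 1))
write_matrix_tsv(cohort$dosage, file.path(out, "dosage.tsv"), c(0, 2))
write_stage_table(panel$truth$regions,
                  file.path(out, "truth_regions.tsv"), "truth_region")

cat(sprintf("seed %d: cohort n = %d, panel n = %d, %d CpGs, %d planted regions\n",
            seed, cfg$n_cohort, cfg$n_panel, cfg$n_cpg, cfg$n_region))
cat(sprintf("ever smokers        %.1f%%\n", 100 * mean(ph$smoking)))
cat(sprintf("drinkers            %.1f%% (median %.1f units/week among drinkers)\n",
            100 * mean(ph$alcohol_units > 0),
            median(ph$alcohol_units[ph$alcohol_units > 0])))
cat(sprintf("HPV16 E6 positive   %.1f%%\n", 100 * mean(ph$hpv)))
cat(sprintf("died by day %d     %.1f%%\n", cfg$censor_day,
            100 * attr(cohort, "event_fraction")))
cat(sprintf("planted: smoking shifts %s beta; mediated log-HR %s per unit average beta\n",
            paste(panel$truth$regions$eff_smoking, collapse = "/"),
            paste(panel$truth$regions$mediation_loghr, collapse = "/")))
cat("wrote results/data/{phenotypes,methylation,dosage,truth_regions}.tsv\n")
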