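#!/usr/bin/env Rscript
# Conservative minimum power for the MR analyses: alpha 0.05, outcome
# sample size 409, over a grid of hazard-ratio values and a range of
# variance-explained (r2) values from 5% to 50% -- r2 from the largest
# single mQTL is a lower bound on the instrument's total variance
# explained, so these curves are minimum power.  Writes results/power.tsv.

suppressMessages(library(ewasmr))

or_grid <- seq(1.0, 3.0, by = 0.1)
r2_grid <- seq(0.05, 0.5, by = 0.05)
tab <- do.call(rbind, lapply(r2_grid, function(r2) {
  cbind(r2 = r2, mr_power(409, r2, or_grid, alpha = 0.05))
}))

dir.create("results", showWarnings = FALSE)
write.table(tab, file.path("results", "power.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
wide <- reshape(tab, idvar = "or", timevar = "r2", direction = "wide")
cat("minimum power at n = 409, alpha = 0.05 (rows: OR; columns: r2):\n")
print(round(wide[wide$or %in% c(1.0, 1.2, 1.5, 2.0, 3.0), ], 3),
      row.names = FALSE)
cat("wrote results/power.tsv\n")
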