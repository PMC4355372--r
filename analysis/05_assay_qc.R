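#!/usr/bin/env Rscript
# Assay quality: robust Z'-factors per screening session and arm (PRKDC
# positive controls vs non-targeting negative controls) and between-screen
# replicate correlations.
#
# Input:  results/screen_normalized.csv
# Output: results/assay_qc.csv, results/replicate_correlation.csv

suppressPackageStartupMessages(library(radscreen))

wells <- read_well_records("results/screen_normalized.csv")

qc <- screen_qc(wells)
write.csv(qc, "results/assay_qc.csv", row.names = FALSE)
cat("robust Z' per (screen, session, arm):\n")
print(qc[, c("screen", "session", "arm", "n_pos", "n_neg", "zprime")], digits = 3,
      row.names = FALSE)
cat(sprintf("\nirradiated arm: median Z' = %.2f (> 0: controls resolvable)\n",
            median(qc$zprime[qc$arm == "ir"])))
cat(sprintf("mock arm:       median Z' = %.2f (< 0: PRKDC knockdown alone not resolvable)\n",
            median(qc$zprime[qc$arm == "mock"])))

rep_cor <- screen_replicate_correlation(wells)
write.csv(rep_cor, "results/replicate_correlation.csv", row.names = FALSE)
cat("\nbetween-screen replicate correlations:\n")
print(rep_cor, digits = 2, row.names = FALSE)
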