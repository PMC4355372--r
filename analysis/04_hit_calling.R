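#!/usr/bin/env Rscript
# Radiosensitizer hit calling: per-siRNA irradiation-by-silencing
# interaction tests against pooled non-targeting controls, BH-FDR at 10%,
# and operating characteristics against the simulation ground truth.
#
# Input:  results/screen_normalized.csv, results/truth_sirna.csv
# Output: results/hits.csv

suppressPackageStartupMessages(library(radscreen))

wells <- read_well_records("results/screen_normalized.csv")
truth <- read.csv("results/truth_sirna.csv", stringsAsFactors = FALSE)

tests <- screen_hit_tests(wells)
hits <- call_hits(tests, fdr_threshold = 0.1)
write.csv(hits[order(hits$q), ], "results/hits.csv", row.names = FALSE)

is_true <- truth$is_sensitizer[match(hits$sirna, truth$sirna)]
tp <- sum(hits$is_hit & is_true)
n_true <- sum(truth$is_sensitizer)
cat(sprintf("tested %d siRNAs; %d hits at FDR <= 0.10 (all sensitizer-direction)\n",
            nrow(hits), sum(hits$is_hit)))
cat(sprintf("ground truth: %d true sensitizers; recall %.2f, empirical FDR %.3f\n",
            n_true, tp / n_true,
            (sum(hits$is_hit) - tp) / max(1, sum(hits$is_hit))))
cat("\nstrongest hits (volcano coordinates: t vs FDR):\n")
print(head(hits[order(hits$q), c("sirna", "estimate", "t", "p", "q", "direction")], 8),
      digits = 3, row.names = FALSE)
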