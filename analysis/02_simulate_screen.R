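#!/usr/bin/env Rscript
# Generate the desk-scale synthetic siRNA screen (2 screens x 2 sessions x
# 10 library plates per set, duplicate +/-4 Gy arms, controls on every
# plate) together with its ground truth, and write the CSV tables the rest
# of the workflow consumes.
#
# Output: results/screen_map.csv, results/screen_counts.csv,
#         results/truth_sirna.csv, results/truth_technical.csv

suppressPackageStartupMessages(library(radscreen))
dir.create("results", showWarnings = FALSE)

seed <- 20260924L
sim <- simulate_screen(sim_params(seed = seed))

write_plate_map(sim$map, "results/screen_map.csv")
write_well_records(sim$wells[, c(names(sim$map), "count")],
                   "results/screen_counts.csv")
write.csv(sim$truth$sirna, "results/truth_sirna.csv", row.names = FALSE)
write.csv(sim$truth$technical, "results/truth_technical.csv", row.names = FALSE)

cat(sprintf("simulated %d wells on %d physical plates (%d siRNAs, %d true sensitizers)\n",
            nrow(sim$wells),
            nrow(unique(sim$map[, c("screen", "session", "plate", "arm")])),
            sum(sim$truth$sirna$role == "sample"),
            sum(sim$truth$sirna$is_sensitizer)))
cat(sprintf("seed %d; counts span %.0f-%.0f cells/well\n",
            seed, min(sim$wells$count), max(sim$wells$count)))
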