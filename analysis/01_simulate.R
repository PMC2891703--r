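#!/usr/bin/env Rscript
# Step 1 — generate the synthetic duplicate screen that the later steps
# analyse: a 2,000-gene single-reporter (firefly) library screened in
# duplicate on 384-well plates under a hypoxia-mimetic stimulus, with 4
# negative (GFP dsRNA) and 4 positive (HIF-alpha dsRNA) control wells per
# plate, 5% planted HIF regulators (knockdown drawn uniformly from
# 0.5-0.95), 5% viability genes depressing both channels, 20% well-level
# noise and 15% (log-scale) plate-to-plate variation.
#
# Writes: results/sim/plates.csv, reagents.csv, ground_truth.tsv

suppressPackageStartupMessages(library(hifscreen))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_genes = 2000, seed = 20100624)
sim <- simulate_screen(cfg)

write_plate_table(sim$dataset, "results/sim/plates.csv")
write.csv(sim$annotation, "results/sim/reagents.csv", row.names = FALSE)
write.table(sim$truth, "results/sim/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

stopifnot(length(validate_dataset(sim$dataset)) == 0)
cat(sprintf("simulated %d wells on %d plates (%d genes: %d planted regulators, %d viability)\n",
            nrow(sim$dataset$wells),
            length(unique(sim$dataset$wells$plate_id)),
            nrow(sim$truth), sum(sim$truth$class == "hif_regulator"),
            sum(sim$truth$class == "viability")))
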