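#!/usr/bin/env Rscript
# Step 3 — phase-I post-processing: remove primary hits whose reporter loss
# is not specific to the hypoxia response. The planted viability genes play
# the role of the cell-viability screen overlap; a random slice of neutral
# hits plays the predicted-only ORF list. Counts are reported per list,
# later lists counted on the running survivors.
#
# Reads:  results/primary_hits.tsv, results/sim/ground_truth.tsv
# Writes: results/filtered_hits.tsv, results/exclusion_report.json

suppressPackageStartupMessages(library(hifscreen))

calls <- read.delim("results/primary_hits.tsv")
truth <- read.delim("results/sim/ground_truth.tsv")
hits <- calls$gene_id[calls$label == "hit"]

viability_list <- truth$gene_id[truth$class == "viability"]
set.seed(3)
predicted_only <- sample(truth$gene_id[truth$class == "neutral"], 100)

report <- apply_exclusions(hits, list(viability = viability_list,
                                      predicted_only = predicted_only))
print(report)

write.table(data.frame(gene_id = report$surviving),
            "results/filtered_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(input = report$input_count, removed = as.list(report$removed),
       surviving = report$surviving_count),
  "results/exclusion_report.json", auto_unbox = TRUE, pretty = TRUE)
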