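#!/usr/bin/env Rscript

## Step 2: floor intensities, drop undetected probes, normalize each donor's
## stimulated samples to that donor's medium control, and select DETs by
## Welch ANOVA + Benjamini-Hochberg. Writes results/dets.tsv and the power
## calculation behind the 8-replicate design.

suppressPackageStartupMessages(library(stimprint))

data_dir <- file.path("results", "data")
m <- read_expression_tsv(file.path(data_dir, "expression.tsv"))
det <- read_expression_tsv(file.path(data_dir, "detection.tsv"))
samples <- read_sample_csv(file.path(data_dir, "samples.csv"))

em <- expression_matrix(m, samples, detection_p = det)
em <- detection_filter(floor_intensities(em))
nm <- normalize_to_medium(em)

dets <- select_dets(nm, nm$samples$stimulus, alpha = 0.05)
write.table(dets, file.path("results", "dets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("probes after detection filter: %d (removed %d)\n",
            nrow(nm$ratios), length(attr(em, "removed_probes"))))
cat(sprintf("DETs kept at FDR 0.05: %d / %d\n", sum(dets$kept), nrow(dets)))
cat(sprintf("replicates needed (alpha 0.05, power 0.8, sd 0.7, fold 2): %d\n",
            power_sample_size(0.05, 0.8, 0.7, 2)))
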