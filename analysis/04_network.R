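#!/usr/bin/env Rscript

## Step 4: weighted coexpression network modules. Prefilters 2-fold induced
## transcripts, collapses replicates to stimulus-level profiles, builds the
## topological overlap dissimilarity, cuts the tree, merges close modules
## and applies the kME filter. Writes the gene labels and the module
## eigengenes.

suppressPackageStartupMessages(library(stimprint))

data_dir <- file.path("results", "data")
m <- read_expression_tsv(file.path(data_dir, "expression.tsv"))
det <- read_expression_tsv(file.path(data_dir, "detection.tsv"))
samples <- read_sample_csv(file.path(data_dir, "samples.csv"))

em <- detection_filter(floor_intensities(expression_matrix(m, samples, det)))
nm <- normalize_to_medium(em)

net <- network_modules(nm, network_config())
labels <- data.frame(gene = names(net$labels), module = unname(net$labels))
write.table(labels, file.path("results", "network_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

if (!is.null(net$eigengenes)) {
  eg <- data.frame(condition = rownames(net$eigengenes),
                   unclass(net$eigengenes), check.names = FALSE)
  write.table(eg, file.path("results", "eigengenes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat(sprintf("soft power: %d; modules: %s\n", net$power,
            paste(names(table(net$labels[net$labels != "unassigned"])),
                  table(net$labels[net$labels != "unassigned"]),
                  sep = "=", collapse = ", ")))
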