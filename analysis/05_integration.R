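#!/usr/bin/env Rscript

## Step 5: integrate the network modules with the protein traits. Correlates
## module eigengenes with log2 trait levels, computes gene significance and
## module membership, selects hub genes (|GS| and |MM| > 0.80), and
## annotates the network modules by percent overlap with the reference
## modules from step 3.

suppressPackageStartupMessages(library(stimprint))

data_dir <- file.path("results", "data")
m <- read_expression_tsv(file.path(data_dir, "expression.tsv"))
det <- read_expression_tsv(file.path(data_dir, "detection.tsv"))
samples <- read_sample_csv(file.path(data_dir, "samples.csv"))
traits <- read_trait_csv(file.path(data_dir, "traits.csv"))

em <- detection_filter(floor_intensities(expression_matrix(m, samples, det)))
nm <- normalize_to_medium(em)
net <- network_modules(nm, network_config())
stopifnot(!is.null(net$eigengenes))

tr <- collapse_replicates(traits)
mt <- module_trait_correlation(net$eigengenes, tr)
long <- data.frame(module = rownames(mt$r)[row(mt$r)],
                   trait = colnames(mt$r)[col(mt$r)],
                   r = as.vector(mt$r), p = as.vector(mt$p),
                   n = as.vector(mt$n))
write.table(long, file.path("results", "module_trait.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

gs <- gene_significance(net$expr, tr)
mm <- module_membership(net$expr, net$eigengenes)
hubs <- do.call(rbind, lapply(colnames(gs), function(t) {
  hub_genes(gs, mm, net$labels, t, threshold = 0.80)
}))
write.table(hubs, file.path("results", "hub_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ref <- read_gmt(file.path("results", "reference_modules.gmt"))
net_sets <- split(names(net$labels), net$labels)
net_sets$unassigned <- NULL
ann <- annotate_by_overlap(net_sets, ref)
write.table(ann$assignments, file.path("results", "module_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("strongest module-trait correlations:\n")
top <- long[order(-abs(long$r)), ]
print(head(top, 4), row.names = FALSE)
cat(sprintf("hub genes: %d; annotated network modules: %d/%d\n",
            nrow(hubs), sum(ann$assignments$reference_module != "unannotated"),
            nrow(ann$assignments)))
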