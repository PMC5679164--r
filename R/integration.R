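## Eigengene-trait integration: replicate collapsing, module-trait Pearson
## correlations, gene significance (GS) and module membership (MM/kME),
## hub-gene selection, and annotation of network modules by overlap with
## reference modules.

#' Collapse replicates to condition-level profiles
#'
#' Averages log2 values within each grouping cell. For expression data the
#' input is a [normalize_to_medium()] result and the output a log2 matrix
#' (probes x cells); for a trait table the output is a condition x trait
#' matrix of mean log2 ratios. Collapsing is idempotent.
#'
#' @param x a `normalized_matrix` or a trait data frame with columns trait,
#'   condition, value (linear ratios > 0; non-positive values are floored to
#'   1e-3 with a warning).
#' @param by "stimulus" (cells are stimuli) or "group_stimulus" (cells are
#'   patient-group x stimulus interactions, labeled "group.stimulus").
#' @return numeric matrix of mean log2 values.
#' @export
collapse_replicates <- function(x, by = c("stimulus", "group_stimulus")) {
  by <- match.arg(by)
  if (inherits(x, "normalized_matrix")) {
    cells <- if (by == "stimulus") x$samples$stimulus else
      paste(x$samples$group, x$samples$stimulus, sep = ".")
    return(.collapse_matrix_log2(x$ratios, cells))
  }
  if (!is.data.frame(x) || !all(c("trait", "condition", "value") %in% names(x))) {
    .fail("x must be a normalized_matrix or a trait table (trait, condition, value)")
  }
  v <- x$value
  if (any(v <= 0)) {
    warning(sprintf("flooring %d non-positive trait value(s) to 1e-3", sum(v <= 0)))
    v[v <= 0] <- 1e-3
  }
  cells <- if (by == "group_stimulus" && "group" %in% names(x)) {
    paste(x$group, x$condition, sep = ".")
  } else x$condition
  lg <- tapply(log2(v), list(cells, x$trait), mean)
  lg[unique(cells), unique(x$trait), drop = FALSE]
}

#' Correlate module eigengenes with protein traits
#'
#' Pearson correlation (with two-sided p-values) between each module
#' eigengene and each log2-transformed trait, over the conditions shared by
#' both matrices. Missing trait values are pairwise-deleted; entries with
#' fewer than 3 complete pairs are reported as NA.
#'
#' @param eg an [module_eigengenes()] matrix (conditions x modules).
#' @param traits numeric matrix of log2 trait values (conditions x traits),
#'   e.g. from [collapse_replicates()].
#' @return list with matrices `r`, `p`, `n` (modules x traits).
#' @export
module_trait_correlation <- function(eg, traits) {
  common <- intersect(rownames(eg), rownames(traits))
  if (length(common) < 3) .fail("need >= 3 aligned conditions")
  eg <- unclass(eg)[common, , drop = FALSE]
  traits <- traits[common, , drop = FALSE]
  r <- matrix(NA_real_, ncol(eg), ncol(traits),
              dimnames = list(colnames(eg), colnames(traits)))
  p <- r; n <- r
  for (i in seq_len(ncol(eg))) for (j in seq_len(ncol(traits))) {
    ok <- is.finite(eg[, i]) & is.finite(traits[, j])
    n[i, j] <- sum(ok)
    if (n[i, j] >= 3) {
      ct <- suppressWarnings(stats::cor.test(eg[ok, i], traits[ok, j]))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}

#' Gene significance (GS)
#'
#' Pearson correlation of each gene's collapsed log2 profile with each
#' log2 trait over aligned conditions. Zero-variance genes get NA.
#'
#' @param x numeric matrix, genes x conditions (log2 scale).
#' @param traits numeric matrix, conditions x traits (log2 scale).
#' @return matrix genes x traits of correlations.
#' @export
gene_significance <- function(x, traits) {
  if (is.null(dim(traits))) traits <- cbind(trait = traits)
  common <- intersect(colnames(x), rownames(traits))
  if (length(common) < 3) .fail("need >= 3 aligned conditions")
  suppressWarnings(stats::cor(t(x[, common, drop = FALSE]),
                              traits[common, , drop = FALSE]))
}

#' Module membership (MM / kME)
#'
#' Pearson correlation of each gene with each module eigengene, for all
#' genes including non-members of a module.
#'
#' @param x numeric matrix, genes x conditions (log2 scale).
#' @param eg an [module_eigengenes()] matrix (conditions x modules).
#' @return matrix genes x modules of correlations.
#' @export
module_membership <- function(x, eg) {
  common <- intersect(colnames(x), rownames(eg))
  suppressWarnings(stats::cor(t(x[, common, drop = FALSE]),
                              unclass(eg)[common, , drop = FALSE]))
}

#' Select hub genes by joint GS/MM thresholds
#'
#' Genes whose absolute gene significance for the chosen trait exceeds
#' `threshold` AND whose absolute module membership for their own module
#' exceeds `threshold`, sorted by |GS| descending (ties by gene id).
#'
#' @param gs matrix from [gene_significance()].
#' @param mm matrix from [module_membership()].
#' @param labels named module labels.
#' @param trait trait column of `gs` to use.
#' @param threshold joint cutoff (default 0.80, strict).
#' @return data frame gene, module, trait, GS, MM.
#' @export
hub_genes <- function(gs, mm, labels, trait, threshold = 0.80) {
  if (!trait %in% colnames(gs)) .fail("trait '%s' not in the GS table", trait)
  genes <- intersect(rownames(gs), rownames(mm))
  genes <- genes[labels[genes] != "unassigned" & !is.na(labels[genes])]
  own_mm <- vapply(genes, function(g) {
    m <- labels[[g]]
    if (m %in% colnames(mm)) mm[g, m] else NA_real_
  }, numeric(1))
  g <- gs[genes, trait]
  ok <- !is.na(g) & !is.na(own_mm) & abs(g) > threshold & abs(own_mm) > threshold
  out <- data.frame(gene = genes[ok], module = unname(labels[genes[ok]]),
                    trait = rep(trait, sum(ok)), GS = unname(g[ok]),
                    MM = unname(own_mm[ok]), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$GS), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate network modules by overlap with reference modules
#'
#' Percent overlap of network module w with reference module r is
#' 100 x |w intersect r| / |w| (the network module is the annotation
#' target; set `denominator = "reference"` for the other convention). Each
#' network module is assigned the best-overlapping reference module's label;
#' a best overlap below `min_overlap` percent yields "unannotated". Argmax
#' ties break toward the lexicographically smallest reference module id.
#'
#' @param network_ms named list (or `module_set`) of network module gene
#'   sets.
#' @param reference_ms named list (or `module_set`) of reference module gene
#'   sets; names may carry annotation labels via attribute `annotation`.
#' @param min_overlap assignment floor in percent (default 10).
#' @param denominator "network" or "reference".
#' @return list with `overlap` (percent matrix, network x reference) and
#'   `assignments` (data frame network_module, reference_module,
#'   percent_overlap, annotation).
#' @export
annotate_by_overlap <- function(network_ms, reference_ms, min_overlap = 10,
                                denominator = c("network", "reference")) {
  denominator <- match.arg(denominator)
  if (inherits(network_ms, "module_set")) network_ms <- unclass(network_ms)
  if (inherits(reference_ms, "module_set")) reference_ms <- unclass(reference_ms)
  anno <- attr(reference_ms, "annotation") %||%
    stats::setNames(names(reference_ms), names(reference_ms))
  if (!length(network_ms) || any(lengths(network_ms) == 0L)) .fail("empty network module")
  if (!length(reference_ms)) .fail("empty reference module set")
  ov <- matrix(0, length(network_ms), length(reference_ms),
               dimnames = list(names(network_ms), names(reference_ms)))
  for (w in names(network_ms)) for (r in names(reference_ms)) {
    inter <- length(intersect(network_ms[[w]], reference_ms[[r]]))
    den <- if (denominator == "network") length(network_ms[[w]]) else length(reference_ms[[r]])
    ov[w, r] <- 100 * inter / den
  }
  refs <- sort(colnames(ov))                       # lexicographic tie-break
  best <- vapply(rownames(ov), function(w) refs[which.max(ov[w, refs])], character(1))
  best_pct <- vapply(rownames(ov), function(w) max(ov[w, ]), numeric(1))
  assigned <- ifelse(best_pct >= min_overlap, best, "unannotated")
  assignments <- data.frame(
    network_module = rownames(ov), reference_module = assigned,
    percent_overlap = best_pct,
    annotation = ifelse(assigned == "unannotated", "unannotated",
                        unname(anno[assigned])),
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(overlap = ov, assignments = assignments)
}
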