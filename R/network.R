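## Weighted coexpression network module detection: induced-transcript
## pre-filter, soft-thresholded adjacency and topological overlap,
## average-linkage tree cut with a size floor and cohesion test, module
## eigengenes, eigengene-based merging, and kME retention filtering.

#' Network analysis configuration
#'
#' @param soft_power soft-thresholding exponent; NULL to auto-pick via
#'   [pick_soft_power()] (falling back to 6 if the fit never reaches the
#'   scale-free criterion on small inputs).
#' @param signed use a signed adjacency ((1 + r)/2)^beta instead of the
#'   default unsigned |r|^beta.
#' @param min_module_size smallest module retained by the tree cut.
#' @param merge_cut_height eigengene dissimilarity (1 - cor) below which
#'   modules are merged.
#' @param min_kme minimum |cor(gene, own module eigengene)| to stay in a
#'   module.
#' @param prefilter_fold induction threshold for the pre-filter.
#' @param cut_fraction static tree-cut height as a fraction of the maximum
#'   merge height.
#' @param max_core_scatter clusters whose mean within-cluster dissimilarity
#'   exceeds this fraction of the cut height are discarded as non-cohesive.
#' @return list of class `network_config`.
#' @export
network_config <- function(soft_power = NULL, signed = FALSE,
                           min_module_size = 30, merge_cut_height = 0.1,
                           min_kme = 0.7, prefilter_fold = 2,
                           cut_fraction = 0.99, max_core_scatter = 0.9) {
  if (!is.null(soft_power)) .assert_scalar_number(soft_power, "soft_power", lower = 1)
  .assert_scalar_number(min_module_size, "min_module_size", lower = 2)
  .assert_scalar_number(merge_cut_height, "merge_cut_height", lower = 0, upper = 1,
                        strict_lower = TRUE)
  if (merge_cut_height >= 1) .fail("merge_cut_height must be in (0, 1)")
  .assert_scalar_number(min_kme, "min_kme", lower = 0, upper = 1, strict_lower = TRUE)
  if (min_kme >= 1) .fail("min_kme must be in (0, 1)")
  .assert_scalar_number(prefilter_fold, "prefilter_fold", lower = 1)
  .assert_scalar_number(cut_fraction, "cut_fraction", lower = 0, upper = 1,
                        strict_lower = TRUE)
  .assert_scalar_number(max_core_scatter, "max_core_scatter", lower = 0, upper = 1)
  structure(list(soft_power = soft_power, signed = signed,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height, min_kme = min_kme,
                 prefilter_fold = prefilter_fold, cut_fraction = cut_fraction,
                 max_core_scatter = max_core_scatter),
            class = "network_config")
}

#' Keep transcripts induced by at least one stimulus
#'
#' Retains transcripts whose condition-level mean ratio (geometric mean over
#' replicates) reaches `fold` for at least one stimulus — the standard
#' pre-filter before network construction, restricting the network to
#' inducible transcripts.
#'
#' @param nm a [normalize_to_medium()] result.
#' @param fold induction threshold (inclusive; default 2).
#' @return the filtered `normalized_matrix`.
#' @export
prefilter_induced <- function(nm, fold = 2) {
  stopifnot(inherits(nm, "normalized_matrix"))
  cond_means <- 2^.collapse_matrix_log2(nm$ratios, nm$samples$stimulus)
  keep <- apply(cond_means, 1, max) >= fold
  if (!any(keep)) .fail("no induced transcripts at fold >= %g", fold)
  nm$ratios <- nm$ratios[keep, , drop = FALSE]
  nm
}

## scale-free topology fit index: R^2 of log10 p(k) ~ log10 k over degree
## bins, zeroed when the slope is positive (hub-poor topologies don't count)
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) n_bins <- max(2L, length(k) %/% 2L)
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) return(0)
  bin <- cut(k, breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.vector(table(bin)) / length(k)
  ok <- pk > 0 & !is.na(dk)
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) 0 else r2
}

#' Pick a soft-thresholding power by the scale-free criterion
#'
#' Returns the smallest candidate power whose scale-free model fit R^2
#' reaches `rsq_cut`; if none does, the candidate maximizing R^2, with a
#' warning. The per-candidate fit table is attached as attribute `fit`.
#'
#' @param x numeric matrix, transcripts x conditions (log2 scale).
#' @param candidates integer powers to try.
#' @param rsq_cut scale-free fit threshold (default 0.8).
#' @param signed use signed adjacency.
#' @return chosen power (with attribute `fit`).
#' @export
pick_soft_power <- function(x, candidates = c(1:10, 12, 14, 16, 18, 20),
                            rsq_cut = 0.8, signed = FALSE) {
  if (!length(candidates)) .fail("candidate list is empty")
  if (nrow(x) < 20) .fail("need >= 20 transcripts to assess scale-free fit")
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) .fail("constant expression: correlation undefined")
  x <- x[sds > 0, , drop = FALSE]
  C <- stats::cor(t(x))
  fit <- vapply(candidates, function(beta) {
    A <- if (signed) ((1 + C) / 2)^beta else abs(C)^beta
    diag(A) <- 0
    .scale_free_fit(rowSums(A))
  }, numeric(1))
  tab <- data.frame(power = candidates, rsq = fit)
  ok <- which(fit >= rsq_cut)
  if (length(ok)) {
    power <- candidates[ok[1]]
  } else {
    power <- candidates[which.max(fit)]
    warning(sprintf("no candidate power reaches scale-free R^2 >= %g (best %.2f at power %d)",
                    rsq_cut, max(fit), power))
  }
  structure(power, fit = tab)
}

#' Topological overlap dissimilarity
#'
#' Soft-thresholded correlation adjacency (unsigned |r|^beta by default,
#' signed ((1 + r)/2)^beta optionally) followed by the topological overlap
#' transform
#' \eqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})};
#' returns the dissimilarity 1 - TOM (symmetric, zero diagonal, values in
#' [0, 1]). Zero-variance transcripts are excluded with a warning.
#'
#' @param x numeric matrix, transcripts x conditions (log2 scale).
#' @param cfg a [network_config()] with `soft_power` set.
#' @return dissimilarity matrix over the retained transcripts.
#' @export
adjacency_tom <- function(x, cfg = network_config(soft_power = 6)) {
  if (is.null(cfg$soft_power)) .fail("soft_power must be resolved before adjacency_tom")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance transcript(s)", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
  }
  C <- stats::cor(t(x))
  A <- if (cfg$signed) ((1 + C) / 2)^cfg$soft_power else abs(C)^cfg$soft_power
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  den <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / den
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0; d[d > 1] <- 1
  (d + t(d)) / 2
}

#' Detect network modules by tree cut
#'
#' Average-linkage hierarchical clustering of the topological overlap
#' dissimilarity, cut statically at `cut_fraction` of the maximum merge
#' height. Branches are kept as modules when they contain at least
#' `min_module_size` transcripts and are cohesive (mean within-branch
#' dissimilarity at most `max_core_scatter` x cut height); all other
#' transcripts are labeled "unassigned". Modules are labeled mod1, mod2, ...
#' by decreasing size.
#'
#' @param diss dissimilarity matrix from [adjacency_tom()].
#' @param cfg a [network_config()].
#' @return named character vector transcript -> module label.
#' @export
detect_modules <- function(diss, cfg = network_config()) {
  ids <- rownames(diss)
  if (nrow(diss) < cfg$min_module_size) {
    warning("fewer transcripts than min_module_size; nothing assigned")
    return(stats::setNames(rep("unassigned", nrow(diss)), ids))
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cut_h <- cfg$cut_fraction * max(hc$height)
  cl <- stats::cutree(hc, h = cut_h)
  labels <- stats::setNames(rep("unassigned", length(ids)), ids)
  kept <- list()
  for (ci in unique(cl)) {
    members <- ids[cl == ci]
    if (length(members) < cfg$min_module_size) next
    scatter <- mean(diss[members, members][upper.tri(matrix(0, length(members), length(members)))])
    if (scatter > cfg$max_core_scatter * cut_h) next
    kept[[length(kept) + 1L]] <- members
  }
  if (length(kept)) {
    kept <- kept[order(-lengths(kept), vapply(kept, min, character(1)))]
    for (i in seq_along(kept)) labels[kept[[i]]] <- sprintf("mod%d", i)
  }
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' members' standardized (per-gene z-scored) log2 profiles across
#' conditions, scaled to unit norm and sign-aligned so its correlation with
#' the module's mean profile is non-negative.
#'
#' @param x numeric matrix, transcripts x conditions (log2 scale).
#' @param labels named module labels from [detect_modules()]; "unassigned"
#'   is ignored.
#' @return matrix conditions x modules (class `eigengene_matrix`), with
#'   attribute `var_explained` (proportion of member variance captured).
#' @export
module_eigengenes <- function(x, labels) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) .fail("no assigned modules")
  eg <- matrix(NA_real_, ncol(x), length(mods),
               dimnames = list(colnames(x), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- names(labels)[labels == m]
    if (length(members) < 2) .fail("module '%s' has < 2 members", m)
    z <- base::scale(t(x[members, , drop = FALSE]))   # conditions x genes
    const <- !is.finite(colSums(z))
    if (all(const)) .fail("module '%s' has only constant members", m)
    if (any(const)) {
      warning(sprintf("module '%s': dropping %d constant member(s) from eigengene", m, sum(const)))
      z <- z[, !const, drop = FALSE]
    }
    sv <- svd(z)
    e <- sv$u[, 1]
    e <- e / sqrt(sum(e^2))
    mean_profile <- rowMeans(z)
    if (stats::sd(mean_profile) > 0 && stats::cor(e, mean_profile) < 0) e <- -e
    eg[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(eg, class = c("eigengene_matrix", "matrix"), var_explained = ve)
}

#' Merge modules with near-identical eigengenes
#'
#' Iteratively merges the module pair with the most correlated eigengenes
#' while their dissimilarity (1 - cor) is below `cut_height`, recomputing
#' eigengenes after each merge, until every pairwise eigengene correlation
#' is at most 1 - cut_height.
#'
#' @param x numeric matrix, transcripts x conditions (log2 scale).
#' @param labels named module labels.
#' @param cut_height merge threshold on 1 - cor (default 0.1).
#' @return list with `labels` and `eigengenes`.
#' @export
merge_close_modules <- function(x, labels, cut_height = 0.1) {
  repeat {
    eg <- module_eigengenes(x, labels)
    if (ncol(eg) < 2) return(list(labels = labels, eigengenes = eg))
    cc <- stats::cor(unclass(eg))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= cut_height) return(list(labels = labels, eigengenes = eg))
    from <- colnames(cc)[max(best)]; into <- colnames(cc)[min(best)]
    labels[labels == from] <- into
  }
}

#' Filter members by eigengene connectivity (kME)
#'
#' Relabels as "unassigned" every transcript whose absolute correlation with
#' its own module's eigengene falls below `min_kme`; modules emptied by the
#' filter are dissolved with a warning, and eigengenes are recomputed once
#' afterwards.
#'
#' @param x numeric matrix, transcripts x conditions (log2 scale).
#' @param labels named module labels.
#' @param eg current [module_eigengenes()] of `labels`.
#' @param min_kme retention threshold (default 0.7).
#' @return list with `labels` and recomputed `eigengenes` (NULL if no module
#'   survives).
#' @export
kme_filter <- function(x, labels, eg, min_kme = 0.7) {
  for (m in colnames(eg)) {
    members <- names(labels)[labels == m]
    kme <- suppressWarnings(
      stats::cor(t(x[members, , drop = FALSE]), unclass(eg)[, m]))[, 1]
    kme[is.na(kme)] <- 0
    drop <- members[abs(kme) < min_kme]
    labels[drop] <- "unassigned"
    if (!any(labels == m)) warning(sprintf("module '%s' dissolved by the kME filter", m))
  }
  if (all(labels == "unassigned")) {
    return(list(labels = labels, eigengenes = NULL))
  }
  list(labels = labels, eigengenes = module_eigengenes(x, labels))
}

#' Full network-module pipeline
#'
#' Pre-filters induced transcripts, collapses replicates, resolves the soft
#' power, builds the topological overlap dissimilarity, cuts the tree,
#' merges close modules and applies the kME filter.
#'
#' @param nm a [normalize_to_medium()] result.
#' @param cfg a [network_config()].
#' @param collapse_by "stimulus" or "group_stimulus".
#' @return list with `labels`, `eigengenes`, `power`, and the collapsed
#'   log2 matrix `expr`.
#' @export
network_modules <- function(nm, cfg = network_config(), collapse_by = "stimulus") {
  nm <- prefilter_induced(nm, cfg$prefilter_fold)
  x <- collapse_replicates(nm, by = collapse_by)
  power <- cfg$soft_power
  if (is.null(power)) {
    power <- tryCatch(suppressWarnings(as.integer(pick_soft_power(x, signed = cfg$signed))),
                      error = function(e) 6L)
    cfg$soft_power <- power
  }
  diss <- adjacency_tom(x, cfg)
  x <- x[rownames(diss), , drop = FALSE]
  labels <- detect_modules(diss, cfg)
  if (all(labels == "unassigned")) {
    return(list(labels = labels, eigengenes = NULL, power = power, expr = x))
  }
  merged <- merge_close_modules(x, labels, cfg$merge_cut_height)
  filtered <- kme_filter(x, merged$labels, merged$eigengenes, cfg$min_kme)
  list(labels = filtered$labels, eigengenes = filtered$eigengenes,
       power = power, expr = x)
}
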