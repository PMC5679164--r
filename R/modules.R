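## Reference-module extraction: per-stimulus coexpression clustering,
## cocluster scoring, and clique-based module assignment; plus the modular
## fingerprint and the molecular distance to medium (MDTM).

#' Cluster transcripts within each stimulus group
#'
#' Partitions transcripts into k coexpression clusters independently for
#' each stimulus group, using k-means on the log2 ratio profiles of the
#' group's samples. With `scale = "sample"` each sample column is
#' standardized first; with `scale = "gene"` each transcript profile is
#' (which removes a uniform induction shared by all of a program's genes —
#' see the package vignette for why "none" is the default under a
#' categorical stimulus design).
#'
#' @param nm a [normalize_to_medium()] result.
#' @param k clusters per stimulus group (>= 2). If k is at least the number
#'   of distinct profiles, clusters degenerate to one per distinct profile.
#' @param scale one of "none", "gene", "sample".
#' @param seed integer seed making the k-means runs reproducible.
#' @param nstart random restarts per k-means run.
#' @return object of class `partition_set`: integer label matrix
#'   (transcripts x stimulus groups) with attribute `n_groups`.
#' @export
cluster_per_stimulus <- function(nm, k = 30, scale = c("none", "gene", "sample"),
                                 seed = 1L, nstart = 5) {
  stopifnot(inherits(nm, "normalized_matrix"))
  scale <- match.arg(scale)
  n <- nrow(nm$ratios)
  if (n < 2L) .fail("need >= 2 transcripts")
  if (k < 2L) .fail("k must be >= 2")
  if (k > n) .fail("k (%d) exceeds the number of transcripts (%d)", k, n)
  stimuli <- unique(nm$samples$stimulus)
  labels <- matrix(NA_integer_, n, length(stimuli),
                   dimnames = list(rownames(nm$ratios), stimuli))
  set.seed(seed)
  for (g in seq_along(stimuli)) {
    x <- log2(nm$ratios[, nm$samples$stimulus == stimuli[g], drop = FALSE])
    if (scale == "gene") {
      x <- t(base::scale(t(x)))
      x[!is.finite(x)] <- 0
    } else if (scale == "sample") {
      x <- base::scale(x)
      x[!is.finite(x)] <- 0
    }
    distinct <- unique(x)
    if (k >= nrow(distinct)) {
      ## forced partition: one cluster per distinct profile
      labels[, g] <- match(apply(x, 1, paste, collapse = "\r"),
                           apply(distinct, 1, paste, collapse = "\r"))
    } else {
      km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50)
      labels[, g] <- km$cluster
    }
  }
  structure(labels, class = "partition_set", n_groups = length(stimuli))
}

#' Cocluster score matrix
#'
#' For every pair of transcripts, counts the number of stimulus groups in
#' which the pair shares a cluster label; with S groups, scores range from 0
#' to S (diagonal S).
#'
#' @param parts a `partition_set` (or an integer label matrix, transcripts x
#'   groups).
#' @return symmetric integer matrix with attribute `n_groups`.
#' @export
cocluster_scores <- function(parts) {
  labels <- unclass(parts)
  if (!is.matrix(labels)) .fail("parts must be a label matrix")
  if (any(is.na(labels))) .fail("every transcript must be labeled in every partition")
  n <- nrow(labels); S <- ncol(labels)
  cc <- matrix(0L, n, n, dimnames = list(rownames(labels), rownames(labels)))
  for (g in seq_len(S)) {
    cc <- cc + outer(labels[, g], labels[, g], "==")
  }
  storage.mode(cc) <- "integer"
  attr(cc, "n_groups") <- S
  cc
}

#' Extract disjoint reference modules from a cocluster matrix
#'
#' Iterates a score threshold t from S (pairs co-clustered in every group,
#' the most conserved pattern) down to `t_min`. At each t, on the graph over
#' still-unassigned transcripts with an edge wherever the cocluster score is
#' >= t, the largest maximal clique of size >= `min_size` is repeatedly
#' extracted as a new module (ties broken toward the lexicographically
#' smallest member set) and its members removed, before t is decremented.
#' Modules are therefore pairwise disjoint: a transcript appears in at most
#' one module.
#'
#' With `expand = TRUE` (the default) the modules found by the threshold
#' scan are treated as cores and consolidated afterwards in two steps that
#' both preserve the invariant that a module is a clique in the `t_min`
#' graph. First, any two modules whose union is still a clique at `t_min`
#' (every cross pair scores >= `t_min`) are merged, highest mean cross
#' score first. Second, each module is grown: unassigned transcripts whose
#' score with *every* current member is >= `t_min` are admitted one at a
#' time (highest mean score to the module first; ties toward the smallest
#' transcript id). This repairs the greedy scan's tendency to lock in a
#' perfectly-conserved core at a high threshold and strand the remaining
#' members of the same coexpression pattern.
#'
#' Exact maximum-clique search is exponential in the worst case; above
#' `component_guard` graph nodes the method falls back to connected
#' components (with a message), which is also available directly via
#' `mode = "components"`.
#'
#' @param cc cocluster matrix from [cocluster_scores()].
#' @param min_size smallest admissible module (>= 2).
#' @param t_min lowest threshold round; defaults to ceiling(S / 3).
#' @param mode "clique" (exact) or "components" (relaxation).
#' @param component_guard node-count guard for the clique mode.
#' @param expand grow each module core with unassigned transcripts that
#'   keep it a clique at `t_min` (default TRUE).
#' @return object of class `module_set`: named list of transcript id
#'   vectors (modules M01, M02, ... in extraction order), with attributes
#'   `unassigned` (transcript ids) and `threshold` (the round at which each
#'   module was formed).
#' @export
extract_modules <- function(cc, min_size = 10, t_min = NULL,
                            mode = c("clique", "components"),
                            component_guard = 5000, expand = TRUE) {
  mode <- match.arg(mode)
  S <- attr(cc, "n_groups") %||% max(cc)
  if (is.null(t_min)) t_min <- ceiling(S / 3)
  if (min_size < 2) .fail("min_size must be >= 2")
  if (t_min < 1 || t_min > S) .fail("t_min must be in [1, %d]", S)
  ids <- sort(rownames(cc))            # canonical order: input-order invariant
  cc <- cc[ids, ids]
  unassigned <- ids
  modules <- list()
  thresholds <- integer()
  for (t in seq(S, t_min)) {
    repeat {
      if (length(unassigned) < min_size) break
      sub <- cc[unassigned, unassigned, drop = FALSE]
      adj <- sub >= t
      diag(adj) <- FALSE
      if (!any(adj)) break
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      use_components <- mode == "components" ||
        (length(unassigned) > component_guard && {
          message(sprintf("extract_modules: %d nodes at t=%d; switching to connected components",
                          length(unassigned), t))
          TRUE
        })
      if (use_components) {
        comp <- igraph::components(g)
        sizes <- comp$csize
        if (max(sizes) < min_size) break
        keep <- which(sizes >= min_size)
        ## largest-first, lexicographic tie-break on the member sets
        members_list <- lapply(keep, function(ci) {
          sort(names(comp$membership)[comp$membership == ci])
        })
        ord <- order(-vapply(members_list, length, integer(1)),
                     vapply(members_list, `[`, character(1), 1))
        for (mi in ord) {
          modules[[length(modules) + 1L]] <- members_list[[mi]]
          thresholds <- c(thresholds, t)
        }
        unassigned <- setdiff(unassigned, unlist(members_list))
        break
      } else {
        cl <- igraph::largest_cliques(g)
        best_size <- length(cl[[1]])
        if (best_size < min_size) break
        member_sets <- lapply(cl, function(v) sort(names(v)))
        key <- vapply(member_sets, paste, character(1), collapse = "\r")
        members <- member_sets[[which.min(rank(key, ties.method = "first"))]]
        modules[[length(modules) + 1L]] <- members
        thresholds <- c(thresholds, t)
        unassigned <- setdiff(unassigned, members)
      }
    }
    if (length(unassigned) < min_size) break
  }
  if (expand && length(modules) > 1) {
    repeat {
      best <- NULL; best_score <- -Inf
      for (i in seq_len(length(modules) - 1L)) for (j in seq(i + 1L, length(modules))) {
        cross <- cc[modules[[i]], modules[[j]], drop = FALSE]
        if (all(cross >= t_min) && mean(cross) > best_score) {
          best <- c(i, j); best_score <- mean(cross)
        }
      }
      if (is.null(best)) break
      modules[[best[1]]] <- sort(c(modules[[best[1]]], modules[[best[2]]]))
      thresholds[best[1]] <- max(thresholds[best])
      modules <- modules[-best[2]]
      thresholds <- thresholds[-best[2]]
    }
  }
  if (expand && length(modules)) {
    for (i in seq_along(modules)) {
      repeat {
        if (!length(unassigned)) break
        sub <- cc[unassigned, modules[[i]], drop = FALSE]
        ok <- apply(sub >= t_min, 1, all)
        if (!any(ok)) break
        cand <- unassigned[ok]
        score <- rowMeans(sub[ok, , drop = FALSE])
        pick <- cand[order(-score, cand)][1]
        modules[[i]] <- sort(c(modules[[i]], pick))
        unassigned <- setdiff(unassigned, pick)
      }
    }
  }
  names(modules) <- sprintf("M%02d", seq_along(modules))
  structure(modules, class = "module_set",
            unassigned = unassigned, threshold = thresholds)
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules (sizes %s), %d unassigned transcripts\n",
              length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-",
              length(attr(x, "unassigned") %||% character())))
  invisible(x)
}

#' Modular fingerprint: percent 2-fold responding transcripts
#'
#' For each module and condition, the percentage of the module's transcripts
#' whose condition-level ratio (geometric mean over the stimulus's
#' replicates) is at least `fold`-fold up, and the percentage at least
#' `fold`-fold down (inclusive thresholds: ratio >= fold counts up, ratio
#' <= 1/fold counts down). Module transcripts absent from the data count in
#' the denominator only (treated as unchanged) when
#' `missing_in_denominator = TRUE`, keeping percentages comparable across
#' datasets.
#'
#' @param ms a `module_set` (or named list of transcript id vectors).
#' @param nm a [normalize_to_medium()] result.
#' @param fold fold-change threshold (default 2).
#' @param missing_in_denominator keep missing transcripts in the
#'   denominator.
#' @return long data frame: module_id, condition, pct_up, pct_down, n_genes.
#' @export
fingerprint <- function(ms, nm, fold = 2, missing_in_denominator = TRUE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (inherits(ms, "module_set")) ms <- unclass(ms)
  if (!length(ms) || any(lengths(ms) == 0L)) .fail("modules must be non-empty")
  cond_means <- 2^.collapse_matrix_log2(nm$ratios, nm$samples$stimulus)
  conditions <- colnames(cond_means)
  rows <- list()
  for (m in names(ms)) {
    genes <- ms[[m]]
    present <- intersect(genes, rownames(cond_means))
    denom <- if (missing_in_denominator) length(genes) else length(present)
    if (denom == 0L) .fail("module '%s' has no transcripts in the data", m)
    v <- cond_means[present, , drop = FALSE]
    rows[[m]] <- data.frame(
      module_id = m, condition = conditions,
      pct_up = 100 * colSums(v >= fold) / denom,
      pct_down = 100 * colSums(v <= 1 / fold) / denom,
      n_genes = length(genes), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Molecular distance to medium (MDTM)
#'
#' Composite per-sample statistic: the sum of absolute signed fold changes
#' that reach at least `fold`-fold (inclusive), over the transcripts
#' considered. Zero when no transcript qualifies.
#'
#' @param ratios numeric vector of one sample's ratios to medium (> 0).
#' @param subset optional transcript ids restricting the sum (requires a
#'   named `ratios` vector).
#' @param fold qualifying threshold on |signed fold change| (default 2).
#' @return non-negative scalar.
#' @export
mdtm <- function(ratios, subset = NULL, fold = 2) {
  if (!is.null(subset)) {
    if (is.null(names(ratios))) .fail("a transcript subset requires named ratios")
    ratios <- ratios[names(ratios) %in% subset]
  }
  if (!length(ratios)) return(0)
  a <- abs(signed_fold_change(ratios))
  sum(a[a >= fold])
}

#' Per-sample MDTM over a normalized matrix
#'
#' @param nm a [normalize_to_medium()] result.
#' @param subset optional transcript ids.
#' @param fold qualifying threshold.
#' @return data frame sample_id, donor_id, stimulus, group, mdtm.
#' @export
mdtm_samples <- function(nm, subset = NULL, fold = 2) {
  stopifnot(inherits(nm, "normalized_matrix"))
  r <- nm$ratios
  if (!is.null(subset)) r <- r[rownames(r) %in% subset, , drop = FALSE]
  sfc <- abs(ifelse(r >= 1, r, 1 / r))
  sfc[sfc < fold] <- 0
  cbind(nm$samples, mdtm = colSums(sfc))
}
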