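## Microarray-style preprocessing: intensity flooring, per-donor
## ratio-to-medium normalization, detection filtering, Welch ANOVA with
## Benjamini-Hochberg correction, and the replicate power calculation.

#' Construct an expression matrix with sample metadata
#'
#' @param intensities numeric matrix, probes x samples, linear scale >= 0;
#'   rownames are probe ids, colnames sample ids.
#' @param samples data frame with columns sample_id, donor_id, stimulus,
#'   group; one row per column of `intensities`, matched by sample_id.
#' @param detection_p optional matrix of detection p-values in [0, 1], same
#'   shape and dimnames as `intensities`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(intensities, samples, detection_p = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    .fail("intensities must be a numeric matrix")
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    .fail("intensities must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(intensities))) .fail("duplicate probe ids")
  if (anyDuplicated(colnames(intensities))) .fail("duplicate sample ids")
  if (any(intensities < 0)) .fail("intensities must be >= 0")
  req <- c("sample_id", "donor_id", "stimulus", "group")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    .fail("samples must be a data frame with columns %s", paste(req, collapse = ", "))
  }
  if (!setequal(samples$sample_id, colnames(intensities))) {
    .fail("sample sheet does not match intensity columns")
  }
  samples <- samples[match(colnames(intensities), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(intensities))) {
      .fail("detection_p must have the same shape as intensities")
    }
    if (any(detection_p < 0 | detection_p > 1)) .fail("detection p-values must be in [0, 1]")
    dimnames(detection_p) <- dimnames(intensities)
  }
  structure(list(intensities = intensities, samples = samples,
                 detection_p = detection_p),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%d donors, %d conditions)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$samples$donor_id)),
              length(unique(x$samples$stimulus)),
              if (is.null(x$detection_p)) "" else ", with detection p-values"))
  invisible(x)
}

#' Floor low signal intensities
#'
#' Replaces every intensity below `floor` by `floor` (default 10), the
#' conventional guard against ratio blow-up from near-background signals.
#'
#' @param m an [expression_matrix()].
#' @param floor non-negative floor value.
#' @return the floored `expression_matrix`.
#' @export
floor_intensities <- function(m, floor = 10) {
  stopifnot(inherits(m, "expression_matrix"))
  .assert_scalar_number(floor, "floor", lower = 0)
  if (any(!is.finite(m$intensities))) .fail("intensities must be finite")
  m$intensities[m$intensities < floor] <- floor
  m
}

#' Normalize each sample to its donor's medium control
#'
#' Divides every stimulated sample by the same donor's unstimulated (medium)
#' sample, probe by probe, removing per-donor baseline variation (and batch
#' effects confounded with donor). Medium samples are dropped from the
#' output.
#'
#' @param m an [expression_matrix()]; every donor must have exactly one
#'   sample with stimulus "medium".
#' @return an object of class `normalized_matrix` with elements `ratios`
#'   (probes x stimulated samples, all > 0) and `samples`.
#' @export
normalize_to_medium <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  med_idx <- which(m$samples$stimulus == "medium")
  med_by_donor <- split(med_idx, m$samples$donor_id[med_idx])
  donors <- unique(m$samples$donor_id)
  n_med <- vapply(donors, function(d) length(med_by_donor[[d]] %||% integer()), integer(1))
  if (any(n_med != 1L)) {
    .fail("each donor needs exactly one medium sample; offending donor: %s",
          donors[which(n_med != 1L)[1]])
  }
  if (any(m$intensities <= 0)) .fail("intensities must be > 0 (floor first)")
  stim <- which(m$samples$stimulus != "medium")
  med_col <- vapply(m$samples$donor_id[stim], function(d) med_by_donor[[d]], integer(1))
  ratios <- m$intensities[, stim, drop = FALSE] / m$intensities[, med_col, drop = FALSE]
  samples <- m$samples[stim, , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(ratios = ratios, samples = samples), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d probes x %d stimulated samples (%d stimuli)\n",
              nrow(x$ratios), ncol(x$ratios), length(unique(x$samples$stimulus))))
  invisible(x)
}

#' Remove probes undetected in every sample
#'
#' Drops exactly the probes whose detection p-value exceeds `threshold` in
#' all samples; a probe detected in at least one sample is kept. Without
#' detection p-values the matrix is returned unchanged with attribute
#' `detection_filter_skipped = TRUE` and a warning.
#'
#' @param m an [expression_matrix()].
#' @param threshold detection p-value cutoff (default 0.01).
#' @return the filtered `expression_matrix`; attribute `removed_probes`
#'   lists the dropped probe ids.
#' @export
detection_filter <- function(m, threshold = 0.01) {
  stopifnot(inherits(m, "expression_matrix"))
  .assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  if (is.null(m$detection_p)) {
    warning("no detection p-values available; detection filter skipped")
    attr(m, "detection_filter_skipped") <- TRUE
    return(m)
  }
  undetected <- rowSums(m$detection_p <= threshold) == 0L
  removed <- rownames(m$intensities)[undetected]
  m$intensities <- m$intensities[!undetected, , drop = FALSE]
  m$detection_p <- m$detection_p[!undetected, , drop = FALSE]
  attr(m, "removed_probes") <- removed
  m
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Textbook Welch F statistic with Welch-Satterthwaite denominator degrees
#' of freedom, for groups with unequal variances. If every group has zero
#' variance the test is degenerate: p = 1 when all group means coincide,
#' p = 0 otherwise, flagged via `degenerate`.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return list with `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
welch_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) .fail("need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) .fail("each group needs >= 2 observations")
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  k <- length(groups)
  if (any(v == 0)) {
    same <- isTRUE(all.equal(max(m), min(m)))
    return(list(F = if (same) 0 else Inf, p = if (same) 1 else 0,
                df1 = k - 1, df2 = NA_real_, degenerate = TRUE))
  }
  w <- n / v
  mw <- sum(w * m) / sum(w)
  num <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sum(w))^2 / (n - 1)) ## Welch's correction term
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  Fstat <- num / den
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = Fstat, p = stats::pf(Fstat, k - 1, df2, lower.tail = FALSE),
       df1 = k - 1, df2 = df2, degenerate = FALSE)
}

## Row-wise Welch ANOVA over a matrix; groups is a factor over columns.
## Returns a data frame F/p/df2/degenerate; vectorized with rowsum().
.welch_anova_rows <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- as.vector(table(groups))
  s <- t(rowsum(t(x), groups))              # probes x groups sums
  ss <- t(rowsum(t(x^2), groups))
  m <- sweep(s, 2, n, "/")
  v <- sweep(ss - sweep(m^2, 2, n, "*"), 2, n - 1, "/")
  v[v < 0] <- 0                             # numerical guard
  degen <- rowSums(v == 0) > 0
  v_safe <- pmax(v, .Machine$double.xmin)
  w <- sweep(1 / v_safe, 2, n, "*")
  sw <- rowSums(w)
  mw <- rowSums(w * m) / sw
  num <- rowSums(w * (m - mw)^2) / (k - 1)
  lambda <- rowSums(sweep((1 - w / sw)^2, 2, n - 1, "/"))
  Fstat <- num / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)
  ## degenerate rows: p = 1 if group means all (numerically) equal, else 0
  if (any(degen)) {
    spread <- apply(m[degen, , drop = FALSE], 1, function(z) max(z) - min(z))
    p[degen] <- ifelse(spread < 1e-12, 1, 0)
    Fstat[degen] <- ifelse(spread < 1e-12, 0, Inf)
  }
  data.frame(F = Fstat, p = p, df2 = df2, degenerate = degen)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, clipped at 1); a thin
#' validated wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) .fail("p must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) .fail("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed transcripts
#'
#' Per-probe Welch ANOVA of log2 ratios across groups, Benjamini-Hochberg
#' correction, and a keep flag at adjusted p < alpha. Degenerate
#' (zero-variance) probes are flagged and never kept silently. Tukey HSD
#' pairwise p-values are computed on request for the kept probes.
#'
#' @param nm a [normalize_to_medium()] result.
#' @param groups factor over the stimulated samples (e.g. stimulus or
#'   patient group); >= 2 levels required.
#' @param alpha significance cutoff on the adjusted p-value.
#' @param tukey if TRUE, attach Tukey HSD pairwise p-values for kept probes.
#' @return a data frame (class `det_result`) with columns probe_id, F, p,
#'   p_adj, kept, degenerate; optional attribute `tukey` (named list of
#'   pairwise p-value vectors).
#' @export
select_dets <- function(nm, groups, alpha = 0.05, tukey = FALSE) {
  stopifnot(inherits(nm, "normalized_matrix"))
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(nm$ratios)) .fail("groups must match the sample columns")
  if (nlevels(groups) < 2L) .fail("need >= 2 groups")
  lg <- log2(nm$ratios)
  res <- .welch_anova_rows(lg, groups)
  res$p_adj <- bh_adjust(res$p)
  res$kept <- res$p_adj < alpha & !res$degenerate
  out <- data.frame(probe_id = rownames(nm$ratios), F = res$F, p = res$p,
                    p_adj = res$p_adj, kept = res$kept,
                    degenerate = res$degenerate, stringsAsFactors = FALSE)
  class(out) <- c("det_result", "data.frame")
  if (tukey && any(out$kept)) {
    tk <- lapply(which(out$kept), function(i) {
      fit <- stats::aov(lg[i, ] ~ groups)
      stats::TukeyHSD(fit)$groups[, "p adj"]
    })
    names(tk) <- out$probe_id[out$kept]
    attr(out, "tukey") <- tk
  }
  out
}

#' Per-group sample size for a two-fold comparison
#'
#' Closed-form normal-approximation sample size for a two-sided two-sample
#' comparison on the log2 scale:
#' \eqn{n = \lceil 2 (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / \log_2(fold)^2 \rceil},
#' with a minimum of 2. With alpha 0.05, power 0.8, SD 0.7 and fold 2 this
#' gives 8 replicates per condition.
#'
#' @param alpha two-sided false-positive rate, in (0, 1).
#' @param power desired power, in (0, 1).
#' @param sd_log2 per-group SD on the log2 scale, > 0.
#' @param fold target fold difference, > 1.
#' @return integer per-group sample size.
#' @export
power_sample_size <- function(alpha = 0.05, power = 0.8, sd_log2 = 0.7, fold = 2) {
  .assert_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) .fail("'alpha' must be < 1")
  .assert_scalar_number(power, "power", lower = 0, upper = 1, strict_lower = TRUE)
  if (power >= 1) .fail("'power' must be < 1")
  .assert_scalar_number(sd_log2, "sd_log2", lower = 0, strict_lower = TRUE)
  .assert_scalar_number(fold, "fold", lower = 1, strict_lower = TRUE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(2 * z^2 * sd_log2^2 / log2(fold)^2)
  max(2L, as.integer(n))
}
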