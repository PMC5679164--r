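#' Signed fold change
#'
#' Maps a positive expression ratio onto the symmetric fold-change scale used
#' throughout the pipeline: a ratio \eqn{v \ge 1} stays \eqn{v}; a ratio
#' \eqn{v < 1} becomes \eqn{-1/v}, so a 2-fold repression is \eqn{-2}. The
#' magnitude is therefore always \eqn{\ge 1}.
#'
#' @param v numeric vector of ratios, all > 0.
#' @return numeric vector of signed fold changes.
#' @examples
#' signed_fold_change(c(4, 1, 0.25)) # 4, 1, -4
#' @export
signed_fold_change <- function(v) {
  if (!is.numeric(v)) stop("ratios must be numeric", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("ratios must be finite and > 0", call. = FALSE)
  }
  ifelse(v >= 1, v, -1 / v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() with a consistent prefix for user-input problems
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .fail("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) .fail("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) .fail("'%s' must be >= %g", name, lower)
  if (x > upper) .fail("'%s' must be <= %g", name, upper)
  invisible(x)
}

## geometric mean of ratios via the log2 scale (the pipeline's working scale)
.geom_mean_ratio <- function(v) 2^mean(log2(v))

## row-wise means of log2 ratios per grouping cell; returns probes x cells
.collapse_matrix_log2 <- function(ratios, cells) {
  stopifnot(ncol(ratios) == length(cells))
  lg <- log2(ratios)
  cells <- as.character(cells)
  levels <- unique(cells)
  out <- vapply(levels, function(cl) {
    rowMeans(lg[, cells == cl, drop = FALSE])
  }, numeric(nrow(ratios)))
  out <- matrix(out, nrow = nrow(ratios),
                dimnames = list(rownames(ratios), levels))
  out
}
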