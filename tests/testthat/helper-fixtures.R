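## Shared fixtures and small independent oracles used across test files.

## adjusted Rand index between two label vectors (direct contingency-table
## formula; independent of any clustering code under test)
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

## build a normalized_matrix directly from a ratio matrix; one donor per
## sample unless a sample sheet is supplied
make_nm <- function(ratios, stimulus = rep("stimA", ncol(ratios)),
                    donor = sprintf("D%02d", seq_len(ncol(ratios)))) {
  if (is.null(rownames(ratios))) rownames(ratios) <- sprintf("P%05d", seq_len(nrow(ratios)))
  if (is.null(colnames(ratios))) colnames(ratios) <- sprintf("S%03d", seq_len(ncol(ratios)))
  structure(list(ratios = ratios,
                 samples = data.frame(sample_id = colnames(ratios),
                                      donor_id = donor, stimulus = stimulus,
                                      group = "healthy",
                                      stringsAsFactors = FALSE)),
            class = "normalized_matrix")
}

## minimal expression_matrix: given intensities for medium and one stimulus
## per donor
make_em <- function(medium, stimulated, stimulus = "lps", detection_p = NULL) {
  nd <- ncol(medium)
  probes <- sprintf("P%05d", seq_len(nrow(medium)))
  intens <- cbind(medium, stimulated)
  colnames(intens) <- c(sprintf("D%02d_medium", seq_len(nd)),
                        sprintf("D%02d_%s", seq_len(ncol(stimulated)), stimulus))
  rownames(intens) <- probes
  samples <- data.frame(
    sample_id = colnames(intens),
    donor_id = c(sprintf("D%02d", seq_len(nd)), sprintf("D%02d", seq_len(ncol(stimulated)))),
    stimulus = c(rep("medium", nd), rep(stimulus, ncol(stimulated))),
    group = "healthy", stringsAsFactors = FALSE)
  expression_matrix(intens, samples, detection_p = detection_p)
}

## correlated transcript block: n_genes sharing a latent factor at
## correlation r, over n_samples observations
make_block <- function(n_genes, n_samples, r, prefix = "G", seed_offset = 0) {
  f <- rnorm(n_samples)
  x <- t(vapply(seq_len(n_genes), function(i) {
    sqrt(r) * f + sqrt(1 - r) * rnorm(n_samples)
  }, numeric(n_samples)))
  rownames(x) <- sprintf("%s%04d", prefix, seq_len(n_genes))
  colnames(x) <- sprintf("C%03d", seq_len(n_samples))
  x
}
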