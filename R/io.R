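## Plain-text I/O: tab-delimited expression matrices (probe_id first
## column), GMT gene sets, sample sheets and trait tables as CSV. All
## readers fail fast on duplicate ids and ragged rows, naming the line.

## shared TSV table reader with ragged-row detection
.read_tsv_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) .fail("%s: empty file", path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    .fail("%s: ragged row at line %d (%d fields, expected %d)",
          path, bad, widths[bad], widths[1])
  }
  cells
}

#' Read an expression matrix from TSV
#'
#' Expects a header whose first column is `probe_id` followed by sample
#' ids; duplicate probe or sample ids and ragged rows are parse errors.
#'
#' @param path file path.
#' @return numeric matrix (probes x samples).
#' @export
read_expression_tsv <- function(path) {
  cells <- .read_tsv_table(path)
  header <- cells[[1]]
  if (header[1] != "probe_id") .fail("%s: first column must be 'probe_id'", path)
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    .fail("%s: duplicated sample column '%s'", path, sample_ids[duplicated(sample_ids)][1])
  }
  probe_ids <- vapply(cells[-1], `[`, character(1), 1)
  if (anyDuplicated(probe_ids)) {
    .fail("%s: duplicated probe id '%s'", path, probe_ids[duplicated(probe_ids)][1])
  }
  vals <- vapply(cells[-1], function(r) as.numeric(r[-1]), numeric(length(sample_ids)))
  m <- if (is.null(dim(vals))) matrix(vals, nrow = 1) else t(vals)
  dimnames(m) <- list(probe_ids, sample_ids)
  if (any(is.na(m))) .fail("%s: non-numeric values", path)
  m
}

#' Write an expression matrix to TSV
#'
#' Values are written with 12 significant digits so a write/read round trip
#' preserves them to that precision.
#'
#' @param m numeric matrix with probe rownames and sample colnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(m, path) {
  header <- paste(c("probe_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 12)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#' A line with a single member is valid.
#'
#' @param path file path.
#' @return named list of character vectors with attribute `annotation`
#'   (the description column, named by set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 3L)
  if (length(short)) .fail("%s: line %d has fewer than 3 fields", path, short[1])
  nm <- vapply(cells, `[`, character(1), 1)
  if (anyDuplicated(nm)) .fail("%s: duplicated set name '%s'", path, nm[duplicated(nm)][1])
  sets <- lapply(cells, function(r) r[-(1:2)])
  names(sets) <- nm
  attr(sets, "annotation") <- stats::setNames(vapply(cells, `[`, character(1), 2), nm)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional description per set (defaults to the set
#'   name, or attribute `annotation` when present).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "annotation") %||% names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Requires columns sample_id, donor_id, stimulus, group; duplicate sample
#' ids are a parse error.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_sample_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "donor_id", "stimulus", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) .fail("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    .fail("%s: duplicated sample_id '%s'", path, df$sample_id[duplicated(df$sample_id)][1])
  }
  df
}

#' @rdname read_sample_csv
#' @param samples data frame to write.
#' @export
write_sample_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read a trait table from CSV
#'
#' Requires columns trait, kind, condition, value.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trait", "kind", "condition", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) .fail("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (!is.numeric(df$value)) .fail("%s: 'value' must be numeric", path)
  df
}

#' @rdname read_trait_csv
#' @param traits data frame to write.
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}
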