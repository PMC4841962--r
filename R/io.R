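#' Read and write pipeline tables
#'
#' Plain-text readers and writers for the tabular formats the pipeline
#' exchanges: a tab-separated count matrix whose first column `mirna_id`
#' holds miRBase-style names and whose remaining columns are subjects; a
#' comma-separated subject metadata table; a tab-separated target-prediction
#' table (`mirna`, `gene`, `score`); and a gene set with one symbol per
#' line. All files are UTF-8 with a mandatory header row (except the gene
#' set).
#'
#' @param path File path.
#' @param counts,metadata,targets Tibbles as produced by the simulation or
#'   analysis stages.
#' @param genes Character vector of gene symbols.
#' @name mirpanel-io
NULL

#' @rdname mirpanel-io
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  names(counts)[1] <- "mirna_id"
  validate_counts(counts_to_matrix(counts))
  counts
}

#' @rdname mirpanel-io
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname mirpanel-io
#' @export
read_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname mirpanel-io
#' @export
write_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path)
  invisible(path)
}

#' @rdname mirpanel-io
#' @export
read_targets <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(mirna = "c", gene = "c",
                                          score = "d"))
}

#' @rdname mirpanel-io
#' @export
write_targets <- function(targets, path) {
  readr::write_tsv(targets, path)
  invisible(path)
}

#' @rdname mirpanel-io
#' @export
read_gene_set <- function(path) {
  x <- readr::read_lines(path)
  x[nzchar(x)]
}

#' @rdname mirpanel-io
#' @export
write_gene_set <- function(genes, path) {
  readr::write_lines(genes, path)
  invisible(path)
}

#' Normalize counts to reads per million
#'
#' Scales each subject column so it sums to one million reads, the
#' normalization applied to the sequencing data before all downstream
#' analysis. The denominator is the total of the supplied count matrix
#' (i.e., total miRNA-mapped reads).
#'
#' @param counts Counts tibble (first column `mirna_id`) or numeric matrix
#'   (features x subjects).
#' @return Object of the same shape with reads-per-million values; every
#'   column sums to 1e6.
#' @export
#' @examples
#' m <- matrix(c(250, 750), 2, dimnames = list(c("a", "b"), "s1"))
#' rpm_normalize(m)
rpm_normalize <- function(counts) {
  is_df <- is.data.frame(counts)
  m <- counts_to_matrix(counts)
  validate_counts(m)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0("Zero-total subject column(s): ",
                 paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  out <- sweep(m, 2, tot, "/") * 1e6
  if (is_df) matrix_to_counts(out) else out
}

#' Detection filter: features present in at least half the samples
#'
#' Retains a feature iff its raw count is positive (detected) in at least
#' `ceiling(n_subjects / 2)` samples, pooling both diagnostic groups --
#' "at least half" rounds up for odd cohort sizes. Returns the retained
#' rows in input order.
#'
#' @param counts Counts tibble or matrix of raw counts.
#' @param min_fraction Detection fraction (default one half).
#' @return Object of the same shape restricted to retained features, with
#'   attribute `retained` holding the retained feature identifiers.
#' @export
detection_filter <- function(counts, min_fraction = 0.5) {
  is_df <- is.data.frame(counts)
  m <- counts_to_matrix(counts)
  need <- ceiling(min_fraction * ncol(m))
  keep <- rowSums(m > 0) >= need
  out <- if (is_df) counts[keep, , drop = FALSE] else m[keep, , drop = FALSE]
  attr(out, "retained") <- rownames(m)[keep]
  out
}

#' Log2 reads-per-million with a pseudocount
#'
#' All mean/SD-based statistics downstream (Z-score difference, Cohen's d,
#' logistic and PLS-DA predictors) operate on `log2(RPM + 1)`; the +1
#' pseudocount keeps zeros finite. Rank-based statistics are invariant to
#' this monotone transform.
#'
#' @param rpm Reads-per-million tibble or matrix from [rpm_normalize()].
#' @return Matrix of log2(RPM + 1) values (features x subjects).
#' @export
log2_rpm <- function(rpm) {
  log2p1(counts_to_matrix(rpm))
}
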