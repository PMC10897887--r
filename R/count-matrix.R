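#' Read a gene-level count matrix
#'
#' Expects a TSV with gene identifiers in the first column and one column of
#' non-negative integer counts per sample; the header row carries the sample
#' identifiers. Fractional, negative or non-numeric cells are rejected —
#' gene-level quantification feeding a negative-binomial model must be
#' integral.
#'
#' @param path Path to the TSV file.
#' @return An integer matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs).
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop_format("count matrix not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop_format("count matrix needs a gene column plus >=1 sample column")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop_format("duplicate gene ids in count matrix: %s",
                paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m)) stop_format("non-numeric cell(s) in count matrix")
  if (any(m < 0)) stop_format("negative count(s) in count matrix")
  if (any(m != round(m))) stop_format("non-integral count(s) in count matrix")
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  m
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: first column `gene_id`, then one column
#' per sample. Reading the written file back reproduces the matrix exactly.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_validation("counts must be a matrix with gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_validation("duplicate gene ids in count matrix")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop_validation("counts must be non-negative integers")
  counts
}

#' Remove low-count, low-frequency genes
#'
#' Keeps exactly the genes whose count exceeds `min_count` in at least
#' `min_samples` samples; everything else is treated as too weakly or too
#' sporadically expressed to model. The defaults drop genes with counts of 10
#' or below (the threshold is exclusive) unless at least two samples clear it.
#' Gene order is preserved and the operation is idempotent.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param min_count Count a sample must exceed (strictly) to support a gene.
#' @param min_samples Minimum number of supporting samples.
#' @return The row-subset count matrix (possibly with zero rows).
#' @export
filter_low_expression <- function(counts, min_count = 10, min_samples = 2) {
  counts <- validate_count_matrix(counts)
  if (nrow(counts) == 0L) return(counts)
  keep <- rowSums(counts > min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Principal component analysis of expression profiles
#'
#' Ordination used for QC: counts are size-factor normalized
#' ([estimate_size_factors()]), transformed as `log2(x + 1)`, and samples
#' (rows of the transposed matrix) are centered but not scaled before
#' [stats::prcomp()]. In this study design the EO/SM tissue contrast dominates
#' PC1 and EOD duration stratifies the EO samples along PC2.
#'
#' @param counts Integer count matrix with at least two samples.
#' @param size_factors Optional per-sample normalization factors; estimated
#'   from `counts` when `NULL`.
#' @return An object of class `pca_expression`: list with `coordinates`
#'   (samples x components score matrix) and `variance_explained`
#'   (non-increasing fractions summing to 1 over all retained components).
#' @export
pca_expression <- function(counts, size_factors = NULL) {
  counts <- validate_count_matrix(counts)
  if (ncol(counts) < 2L)
    stop_validation("pca_expression needs at least 2 samples")
  sf <- size_factors %||% estimate_size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  x <- t(log2(norm + 1))
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(coordinates = fit$x, variance_explained = ve),
            class = "pca_expression")
}

#' @export
print.pca_expression <- function(x, ...) {
  cat(sprintf("PCA of %d samples, %d components\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  ve <- round(100 * x$variance_explained[seq_len(min(5L, length(x$variance_explained)))], 1)
  cat("variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$variance_explained) > 5L) "..." else "", "\n")
  invisible(x)
}
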