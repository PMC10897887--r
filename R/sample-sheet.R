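#' Read and validate a sample sheet
#'
#' The sample sheet describes one sequencing sample per row. Required columns:
#'
#' * `sample_id` — unique identifier, matching count-matrix and VCF columns.
#' * `cohort` — species or hybrid cohort label (e.g. `com`, `tsh`, `rhy`,
#'   `com_x_tsh`, `com_x_rhy`).
#' * `tissue` — `"EO"` (electric organ) or `"SM"` (skeletal muscle).
#' * `duration_ms` — EOD duration of the cohort, in milliseconds; must be a
#'   positive number and identical for all samples of a cohort.
#' * `replicate` — positive integer replicate index within cohort × tissue.
#' * `role` — `"parent_A"`, `"parent_B"`, `"hybrid"` or `"none"`; used by the
#'   allele-specific stage to orient parental alleles. All samples of a cohort
#'   must share one role.
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#' @return A `data.frame` with the columns above, one row per sample.
#' @examples
#' sheet <- simulate_experiment(sim_config(n_genes = 10))$samples
#' tf <- tempfile(fileext = ".tsv")
#' write_sample_sheet(sheet, tf)
#' identical(read_sample_sheet(tf), sheet)
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_format("sample sheet not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_format("sample sheet is empty: %s", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_sample_sheet(df)
}

#' Write a sample sheet as TSV
#'
#' @param samples A validated sample sheet `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  samples <- validate_sample_sheet(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @param samples A `data.frame` to validate in place of reading a file.
#' @export
validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "cohort", "tissue", "duration_ms",
                "replicate", "role")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L)
    stop_format("sample sheet lacks required column(s): %s",
                paste(missing, collapse = ", "))
  if (nrow(samples) == 0L)
    stop_format("sample sheet has no samples")
  samples <- samples[, required, drop = FALSE]
  samples$sample_id <- as.character(samples$sample_id)
  samples$cohort <- as.character(samples$cohort)
  samples$tissue <- as.character(samples$tissue)
  samples$role <- as.character(samples$role)

  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0L)
    stop_validation("duplicate sample_id: %s", paste(unique(dup), collapse = ", "))
  bad_tissue <- setdiff(unique(samples$tissue), c("EO", "SM"))
  if (length(bad_tissue) > 0L)
    stop_validation("unknown tissue token(s): %s (expected EO or SM)",
                    paste(bad_tissue, collapse = ", "))
  bad_role <- setdiff(unique(samples$role),
                      c("parent_A", "parent_B", "hybrid", "none"))
  if (length(bad_role) > 0L)
    stop_validation("unknown role token(s): %s", paste(bad_role, collapse = ", "))
  samples$duration_ms <- suppressWarnings(as.numeric(samples$duration_ms))
  if (anyNA(samples$duration_ms) || any(samples$duration_ms <= 0))
    stop_validation("duration_ms must be a positive number for every sample")
  rep_num <- suppressWarnings(as.numeric(samples$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop_validation("replicate must be a positive integer")
  samples$replicate <- as.integer(rep_num)

  for (co in unique(samples$cohort)) {
    rows <- samples[samples$cohort == co, ]
    if (length(unique(rows$duration_ms)) > 1L)
      stop_validation("cohort '%s' has inconsistent duration_ms values", co)
    if (length(unique(rows$role)) > 1L)
      stop_validation("cohort '%s' has inconsistent role labels", co)
  }
  rownames(samples) <- NULL
  samples
}

# Subset a sheet to the rows describing given sample ids, preserving id order.
samples_for <- function(samples, sample_ids) {
  idx <- match(sample_ids, samples$sample_id)
  if (anyNA(idx))
    stop_validation("sample(s) absent from sample sheet: %s",
                    paste(sample_ids[is.na(idx)], collapse = ", "))
  samples[idx, , drop = FALSE]
}
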