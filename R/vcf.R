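#' Variant sets
#'
#' Variants called against transcript/CDS coordinates are held in a columnar
#' `variant_set`: the `CHROM` field carries the gene/transcript identifier, so
#' no separate gene-to-coordinate map is needed. Per-sample genotypes (`GT`)
#' and allelic depths (`AD`) are kept as character matrices in VCF notation
#' (`"0/1"`, `"12,30"`), with `NA` for missing values; [parse_gt()] and
#' [ad_depths()] decode them on demand.
#'
#' @param chrom,pos,ref,alt,qual Site-level vectors; `alt` is a list of
#'   character vectors (one or more ALT alleles per site).
#' @param gt,ad Character matrices, sites x samples.
#' @param samples Character vector of sample ids (column names of `gt`/`ad`).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, qual, gt, ad, samples) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(qual) == n)
  gt <- matrix(as.character(gt), nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  ad <- matrix(as.character(ad), nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = alt, qual = as.numeric(qual),
                 gt = gt, ad = ad, samples = as.character(samples)),
            class = "variant_set")
}

#' @export
length.variant_set <- function(x) length(x$chrom)

#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], x$qual[i],
              x$gt[i, , drop = FALSE], x$ad[i, , drop = FALSE], x$samples)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d site(s) on %d gene(s), %d sample(s)\n",
              length(x), length(unique(x$chrom)), length(x$samples)))
  invisible(x)
}

#' Decode a VCF genotype string
#'
#' @param gt Genotype string such as `"0/1"` or `"1|1"`; `NA` or `"./."` for
#'   missing.
#' @return Integer vector of allele indices, or `NULL` when missing.
#' @export
parse_gt <- function(gt) {
  if (is.na(gt)) return(NULL)
  parts <- strsplit(gt, "[/|]")[[1L]]
  if (any(parts == ".")) return(NULL)
  as.integer(parts)
}

#' Decode a VCF allelic-depth string
#'
#' @param ad AD string such as `"12,30"`; `NA` or `"."` for missing.
#' @return Integer vector of per-allele depths (REF first), or `NULL`.
#' @export
ad_depths <- function(ad) {
  if (is.na(ad) || ad == ".") return(NULL)
  as.integer(strsplit(ad, ",", fixed = TRUE)[[1L]])
}

#' Read a multi-sample VCF with GT and AD
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) into a [variant_set()]. Missing
#' genotypes (`./.`) stay missing — they are never read as reference. When a
#' sample sheet is supplied, every sample column in the VCF must appear in it.
#' An AD entry whose arity does not equal 1 + number of ALT alleles is a
#' record-level defect: it is masked to missing and reported in a warning that
#' carries the 1-based line number in the file.
#'
#' @param path Path to the VCF file.
#' @param samples Optional sample sheet ([read_sample_sheet()]) used to
#'   validate the VCF sample columns.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop_format("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(variant_set(character(), integer(), character(), list(),
                       numeric(), matrix(character(), 0L, 0L),
                       matrix(character(), 0L, 0L),
                       colnames(v@gt)[-1L] %||% character()))
  }
  sample_ids <- colnames(v@gt)[-1L]
  if (!is.null(samples)) {
    unknown <- setdiff(sample_ids, samples$sample_id)
    if (length(unknown) > 0L)
      stop_validation("VCF sample(s) absent from sample sheet: %s",
                      paste(unknown, collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dimnames(gt) <- list(NULL, sample_ids)
  dimnames(ad) <- list(NULL, sample_ids)
  alt <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0

  # AD arity must be 1 + number of ALT alleles; offenders are masked and
  # reported with their line number in the file.
  n_alleles <- lengths(alt) + 1L
  arity <- matrix(0L, nrow(ad), ncol(ad))
  ok <- !is.na(ad) & ad != "."
  arity[ok] <- lengths(regmatches(ad[ok], gregexpr(",", ad[ok], fixed = TRUE))) + 1L
  bad <- ok & (arity != n_alleles)
  if (any(bad)) {
    n_meta <- length(v@meta)
    bad_sites <- which(rowSums(bad) > 0L)
    lines <- n_meta + 1L + bad_sites   # meta block + #CHROM header + site index
    warning(sprintf("malformed AD arity at VCF line(s) %s; entries set to missing",
                    paste(lines, collapse = ", ")))
    ad[bad] <- NA_character_
  }
  ad[!is.na(ad) & ad == "."] <- NA_character_
  variant_set(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
              alt, qual, gt, ad, sample_ids)
}

#' Write a variant set as VCF v4.2
#'
#' Emits the same plain-text dialect [read_vcf()] consumes: `GT:AD` per
#' sample, `./.` and `.` for missing values. Used by the synthetic-data
#' generator; output is byte-deterministic for a given input.
#'
#' @param x A [variant_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "variant_set"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=electroase",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (REF first)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  n <- length(x)
  lines <- character(n)
  for (i in seq_len(n)) {
    gt <- x$gt[i, ]
    ad <- x$ad[i, ]
    cells <- paste(ifelse(is.na(gt), "./.", gt), ifelse(is.na(ad), ".", ad),
                   sep = ":")
    lines[i] <- paste(c(x$chrom[i], x$pos[i], ".", x$ref[i],
                        paste(x$alt[[i]], collapse = ","),
                        format(x$qual[i], trim = TRUE, scientific = FALSE,
                               digits = 15),
                        ".", ".", "GT:AD", cells), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
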