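#' Keep called biallelic SNPs
#'
#' Mirrors the `bcftools view --exclude-uncalled -m2 -M2` step: retains sites
#' with exactly one ALT allele, single-nucleotide REF and ALT, and at least
#' one called genotype.
#'
#' @param variants A [variant_set()].
#' @return The filtered [variant_set()].
#' @export
filter_biallelic <- function(variants) {
  stopifnot(inherits(variants, "variant_set"))
  if (length(variants) == 0L) return(variants)
  nucs <- c("A", "C", "G", "T")
  keep <- vapply(seq_len(length(variants)), function(i) {
    alt <- variants$alt[[i]]
    length(alt) == 1L &&
      variants$ref[i] %in% nucs && alt %in% nucs &&
      any(!is.na(variants$gt[i, ]))
  }, TRUE)
  variants[keep]
}

#' Quality and depth filtering of biallelic SNPs
#'
#' Removes sites whose `QUAL` is strictly below `qual_min` (70 by default, so
#' QUAL = 70 is retained). Allelic depth is then screened per hybrid
#' individual: under the default `depth_rule = "each"` an observation fails
#' when either allele's depth is below `depth_min` (both alleles need
#' coverage for a meaningful proportion); `depth_rule = "both"` is the
#' literal reading in which an observation fails only when both alleles are
#' below the threshold. Failing observations are masked (that individual
#' contributes nothing downstream) and a site survives only if at least one
#' hybrid individual passes. Parents contribute genotypes, not depths, so no
#' depth requirement applies to them. An AD missing where the genotype is
#' called counts as a failure and is reported in a warning.
#'
#' @param variants Biallelic [variant_set()].
#' @param samples Sample sheet identifying the hybrid samples (`role ==
#'   "hybrid"`).
#' @param qual_min Minimum site QUAL (inclusive).
#' @param depth_min Minimum allelic depth (inclusive).
#' @param depth_rule `"each"` (default) or `"both"`; see Details.
#' @return The filtered [variant_set()] with failing hybrid AD entries
#'   masked to missing.
#' @export
filter_quality <- function(variants, samples, qual_min = 70, depth_min = 10,
                           depth_rule = c("each", "both")) {
  stopifnot(inherits(variants, "variant_set"))
  depth_rule <- match.arg(depth_rule)
  variants <- variants[variants$qual >= qual_min]
  if (length(variants) == 0L) return(variants)
  sheet <- samples_for(samples, variants$samples)
  hybrid_cols <- which(sheet$role == "hybrid")
  if (length(hybrid_cols) == 0L) return(variants)

  n_missing_ad <- 0L
  pass_any <- rep(FALSE, length(variants))
  for (i in seq_len(length(variants))) {
    for (s in hybrid_cols) {
      gt_called <- !is.na(variants$gt[i, s])
      d <- ad_depths(variants$ad[i, s])
      if (is.null(d)) {
        if (gt_called) n_missing_ad <- n_missing_ad + 1L
        variants$ad[i, s] <- NA_character_
        next
      }
      fails <- if (depth_rule == "each") any(d < depth_min) else all(d < depth_min)
      if (fails) variants$ad[i, s] <- NA_character_ else pass_any[i] <- TRUE
    }
  }
  if (n_missing_ad > 0L)
    warning(sprintf("%d called hybrid genotype(s) lacked AD and were dropped",
                    n_missing_ad))
  variants[pass_any]
}

#' Identify fixed parental biallelic SNPs
#'
#' A site is fixed between the parental species when every parent-A sample is
#' homozygous for one allele and every parent-B sample homozygous for the
#' other, with no missing parental genotype (missing genotypes are never
#' imputed). `allele_A` records the allele carried by parent A — the com
#' allele — whether it is REF or ALT; downstream proportions are therefore
#' invariant to REF/ALT orientation. At a fixed site every F1 hybrid is
#' obligate heterozygous, so read origin is unambiguous.
#'
#' @param variants Quality-filtered biallelic [variant_set()].
#' @param samples Sample sheet; parent samples are found by `role` (and
#'   optionally restricted by cohort).
#' @param parent_a_cohort,parent_b_cohort Optional cohort names selecting
#'   which parental cohorts define the contrast (defaults: all `parent_A` /
#'   `parent_B` samples).
#' @return `data.frame`: `gene_id`, `pos`, `allele_A`, `allele_B`,
#'   `a_index` (0 = REF, 1 = ALT), `qual`.
#' @export
identify_fixed_snps <- function(variants, samples,
                                parent_a_cohort = NULL, parent_b_cohort = NULL) {
  stopifnot(inherits(variants, "variant_set"))
  sheet <- samples_for(samples, variants$samples)
  a_cols <- which(sheet$role == "parent_A" &
                    (is.null(parent_a_cohort) | sheet$cohort %in% parent_a_cohort))
  b_cols <- which(sheet$role == "parent_B" &
                    (is.null(parent_b_cohort) | sheet$cohort %in% parent_b_cohort))
  if (length(a_cols) == 0L || length(b_cols) == 0L)
    stop_validation("both parental cohorts must be present in the VCF/sample sheet")

  hom_allele <- function(gts) {
    # shared homozygous allele index across samples, or NA
    alleles <- integer(0)
    for (gt in gts) {
      g <- parse_gt(gt)
      if (is.null(g) || length(unique(g)) != 1L) return(NA_integer_)
      alleles <- c(alleles, g[1L])
    }
    if (length(unique(alleles)) == 1L) alleles[1L] else NA_integer_
  }

  out <- list()
  for (i in seq_len(length(variants))) {
    a <- hom_allele(variants$gt[i, a_cols])
    b <- hom_allele(variants$gt[i, b_cols])
    if (is.na(a) || is.na(b) || a == b) next
    alleles <- c(variants$ref[i], variants$alt[[i]])
    out[[length(out) + 1L]] <- data.frame(
      gene_id = variants$chrom[i], pos = variants$pos[i],
      allele_A = alleles[a + 1L], allele_B = alleles[b + 1L],
      a_index = a, qual = variants$qual[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), pos = integer(),
                      allele_A = character(), allele_B = character(),
                      a_index = integer(), qual = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-individual com-allele expression proportions
#'
#' For every gene x hybrid individual, computes at each fixed SNP the
#' proportion `depth(allele_A) / (depth(allele_A) + depth(allele_B))` and
#' aggregates SNPs within the individual by an unweighted mean of per-SNP
#' proportions (reads are also summed for reporting, but the proportion is
#' the mean of proportions, not the pooled-read ratio). SNPs with masked or
#' zero-depth AD are skipped for that individual.
#'
#' @param fixed Output of [identify_fixed_snps()].
#' @param variants The [variant_set()] holding the allelic depths.
#' @param samples Sample sheet.
#' @param hybrid_cohort Cohort label of the hybrid individuals to evaluate.
#' @param tissue Optional tissue restriction (`"EO"` or `"SM"`).
#' @param aggregate `"mean"` (default) or `"pooled"` (depth-weighted ratio of
#'   summed reads).
#' @return `data.frame`: `gene_id`, `sample_id`, `cohort`, `tissue`,
#'   `n_snps`, `reads_A`, `reads_B`, `proportion_A`.
#' @export
allelic_proportions <- function(fixed, variants, samples, hybrid_cohort,
                                tissue = NULL, aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (nrow(fixed) == 0L) stop_validation("no fixed SNPs supplied")
  sheet <- samples_for(samples, variants$samples)
  sel <- sheet$cohort == hybrid_cohort
  if (!is.null(tissue)) sel <- sel & sheet$tissue %in% tissue
  cols <- which(sel)
  if (length(cols) == 0L)
    stop_validation("no samples for hybrid cohort '%s'%s", hybrid_cohort,
                    if (is.null(tissue)) "" else sprintf(" in tissue %s", tissue))
  key <- paste(variants$chrom, variants$pos)
  site_idx <- match(paste(fixed$gene_id, fixed$pos), key)
  if (anyNA(site_idx))
    stop_validation("fixed SNP(s) absent from variant set")

  out <- list()
  for (gene in unique(fixed$gene_id)) {
    rows <- which(fixed$gene_id == gene)
    for (s in cols) {
      props <- numeric(0); ra <- 0L; rb <- 0L
      for (r in rows) {
        i <- site_idx[r]
        d <- ad_depths(variants$ad[i, s])
        if (is.null(d) || length(d) < 2L) next
        da <- d[fixed$a_index[r] + 1L]
        db <- d[2L - fixed$a_index[r]]
        if (da + db == 0L) next
        props <- c(props, da / (da + db))
        ra <- ra + da; rb <- rb + db
      }
      if (length(props) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene, sample_id = sheet$sample_id[s],
        cohort = sheet$cohort[s], tissue = sheet$tissue[s],
        n_snps = length(props), reads_A = ra, reads_B = rb,
        proportion_A = if (aggregate == "mean") mean(props) else ra / (ra + rb),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), sample_id = character(),
                      cohort = character(), tissue = character(),
                      n_snps = integer(), reads_A = integer(),
                      reads_B = integer(), proportion_A = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify allelic expression imbalance
#'
#' Summarizes per-individual com-allele proportions per gene (within one
#' hybrid cohort and tissue) and applies both imbalance rules side by side:
#'
#' * mean rule (the headline call): the across-individual mean proportion is
#'   strictly below `low` (0.4) or strictly above `high` (0.6);
#' * all-individuals rule: every individual shows > `high` of the same
#'   parental allele (i.e. all proportions > `high`, or all < `1 - high`).
#'
#' The 95% confidence interval is Student-t on the individual-level
#' proportions (biological replicates); genes observed in a single
#' individual are reported with missing CI limits.
#'
#' @param observations Output of [allelic_proportions()].
#' @param low,high Strict imbalance bounds on the mean (defaults 0.4 / 0.6).
#' @param conf_level Confidence level for the interval.
#' @return `data.frame`: `gene_id`, `cohort`, `tissue`,
#'   `mean_proportion_A`, `ci_low`, `ci_high`, `n_individuals`, `n_snps`,
#'   `imbalanced_mean_rule`, `imbalanced_all_individuals_rule`, `direction`
#'   (`A_biased` / `B_biased` / `balanced`).
#' @export
classify_aei <- function(observations, low = 0.4, high = 0.6,
                         conf_level = 0.95) {
  if (low >= 0.5 || high <= 0.5)
    stop_validation("imbalance bounds must satisfy low < 0.5 < high")
  if (nrow(observations) == 0L)
    return(data.frame(gene_id = character(), cohort = character(),
                      tissue = character(), mean_proportion_A = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      n_individuals = integer(), n_snps = integer(),
                      imbalanced_mean_rule = logical(),
                      imbalanced_all_individuals_rule = logical(),
                      direction = character(), stringsAsFactors = FALSE))
  grp <- interaction(observations$gene_id, observations$cohort,
                     observations$tissue, drop = TRUE, sep = "\r")
  out <- lapply(split(observations, grp), function(d) {
    p <- d$proportion_A
    n <- length(p)
    m <- mean(p)
    if (n >= 2L) {
      half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L) *
        stats::sd(p) / sqrt(n)
      ci <- c(m - half, m + half)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(
      gene_id = d$gene_id[1L], cohort = d$cohort[1L], tissue = d$tissue[1L],
      mean_proportion_A = m, ci_low = ci[1L], ci_high = ci[2L],
      n_individuals = n, n_snps = max(d$n_snps),
      imbalanced_mean_rule = (m < low || m > high),
      imbalanced_all_individuals_rule = all(p > high) || all(p < 1 - high),
      direction = if (m > high) "A_biased" else if (m < low) "B_biased" else "balanced",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cohort, res$tissue, res$gene_id), , drop = FALSE]
}

#' Compare the protein alleles encoded by two coding sequences
#'
#' Translates two equal-length, in-frame coding sequences with the standard
#' genetic code and reports the amino-acid positions where they differ
#' (1-based). A single trailing stop codon (present in both sequences) is
#' tolerated; internal stops or frame problems are validation errors, since
#' they indicate the inputs are not comparable CDS alleles.
#'
#' @param cds_a,cds_b Nucleotide sequences (character strings or
#'   [Biostrings::DNAString] objects) of the two alleles.
#' @return `data.frame`: `site` (amino-acid position), `residue_a`,
#'   `residue_b`.
#' @export
compare_protein_alleles <- function(cds_a, cds_b) {
  a <- toupper(as.character(cds_a))
  b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b))
    stop_validation("coding sequences differ in length (%d vs %d)",
                    nchar(a), nchar(b))
  if (nchar(a) %% 3L != 0L)
    stop_validation("coding sequence length %d is not divisible by 3", nchar(a))
  if (nchar(a) == 0L) stop_validation("empty coding sequence")
  translate1 <- function(s) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("*", aa, fixed = TRUE))
      stop_validation("internal stop codon in coding sequence")
    aa
  }
  pa <- translate1(a)
  pb <- translate1(b)
  if (nchar(pa) != nchar(pb))
    stop_validation("alleles disagree on the position of the stop codon")
  ra <- strsplit(pa, "")[[1L]]
  rb <- strsplit(pb, "")[[1L]]
  diff <- which(ra != rb)
  data.frame(site = diff, residue_a = ra[diff], residue_b = rb[diff],
             stringsAsFactors = FALSE, row.names = NULL)
}
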