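# Shared fixture builders: everything is generated in code at test time.

# Minimal two-group sample sheet for a count matrix with columns A_*, B_*.
two_group_sheet <- function(counts, cohort = "sim") {
  ids <- colnames(counts)
  data.frame(sample_id = ids, cohort = cohort,
             tissue = ifelse(grepl("^A", ids), "EO", "SM"),
             duration_ms = 1,
             replicate = as.integer(sub("^[AB]_", "", ids)),
             role = "none", stringsAsFactors = FALSE)
}

# Purebred three-cohort sheet mirroring the study shape (5/3/5 per tissue).
purebred_sheet <- function() {
  reps <- c(com = 5L, tsh = 3L, rhy = 5L)
  durs <- c(com = 0.4, tsh = 5, rhy = 40)
  roles <- c(com = "parent_A", tsh = "parent_B", rhy = "parent_B")
  out <- do.call(rbind, lapply(names(reps), function(co) {
    g <- expand.grid(tissue = c("EO", "SM"), replicate = seq_len(reps[co]),
                     stringsAsFactors = FALSE)
    data.frame(sample_id = sprintf("%s_%s_%d", co, g$tissue, g$replicate),
               cohort = co, tissue = g$tissue, duration_ms = durs[co],
               replicate = g$replicate, role = roles[co],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

# NB counts for a purebred design with per-gene EO offset and EO duration
# slope (log2 per duration step); slope NA means a null-interaction gene.
purebred_counts <- function(n_genes, sheet, mean_base = 200, dispersion = 0.05,
                            eo_lfc = 0, eo_slope_per_step = 0, seed = 1) {
  set.seed(seed)
  step <- match(sheet$duration_ms, sort(unique(sheet$duration_ms))) - 1L
  is_eo <- sheet$tissue == "EO"
  counts <- t(vapply(seq_len(n_genes), function(g) {
    mu <- mean_base * 2^(eo_lfc * is_eo + eo_slope_per_step * step * is_eo)
    stats::rnbinom(nrow(sheet), mu = mu, size = 1 / dispersion)
  }, numeric(nrow(sheet))))
  dimnames(counts) <- list(sprintf("g%05d", seq_len(n_genes)), sheet$sample_id)
  storage.mode(counts) <- "integer"
  counts
}

# A 20-site toy variant set covering every filter code path: clean fixed
# SNPs (including com-allele = ALT), multiallelic, indel, QUAL 69/70
# boundary, low-depth, non-fixed and missing-parental-genotype sites.
# Samples: 2 parent_A, 2 parent_B, 3 hybrids.
toy_ase_fixture <- function() {
  samples <- data.frame(
    sample_id = c("pa1", "pa2", "pb1", "pb2", "h1", "h2", "h3"),
    cohort = c("com", "com", "tsh", "tsh", "com_x_tsh", "com_x_tsh", "com_x_tsh"),
    tissue = "EO", duration_ms = c(0.4, 0.4, 5, 5, 0.4, 0.4, 0.4),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L, 3L),
    role = c("parent_A", "parent_A", "parent_B", "parent_B",
             "hybrid", "hybrid", "hybrid"),
    stringsAsFactors = FALSE)

  site <- function(chrom, pos, ref, alt, qual, gt, ad) {
    list(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
         gt = gt, ad = ad)
  }
  hom0 <- "0/0"; hom1 <- "1/1"; het <- "0/1"
  sites <- list(
    # 1-3: clean fixed SNPs, com allele = REF
    site("geneA", 10, "A", "G", 120, c(hom0, hom0, hom1, hom1, het, het, het),
         c("50,0", "48,0", "0,52", "0,47", "30,70", "28,72", "33,67")),
    site("geneA", 20, "C", "T", 90, c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0", "42,0", "0,39", "0,44", "25,75", "24,76", "27,73")),
    site("geneB", 15, "G", "A", 150, c(hom0, hom0, hom1, hom1, het, het, het),
         c("60,0", "55,0", "0,58", "0,61", "80,20", "82,18", "78,22")),
    # 4: fixed SNP with com allele = ALT (orientation case)
    site("geneC", 12, "T", "C", 110, c(hom1, hom1, hom0, hom0, het, het, het),
         c("0,45", "0,50", "52,0", "49,0", "40,60", "38,62", "41,59")),
    # 5: QUAL exactly 70 (retained)
    site("geneD", 8, "A", "C", 70, c(hom0, hom0, hom1, hom1, het, het, het),
         c("30,0", "31,0", "0,29", "0,33", "15,15", "16,14", "15,16")),
    # 6: QUAL 69 (removed)
    site("geneD", 16, "G", "T", 69, c(hom0, hom0, hom1, hom1, het, het, het),
         c("30,0", "31,0", "0,29", "0,33", "15,15", "16,14", "15,16")),
    # 7: multiallelic (removed by biallelic filter)
    site("geneE", 5, "A", c("G", "T"), 200,
         c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0,0", "41,0,0", "0,39,0", "0,42,0", "20,20,0", "21,19,0", "22,18,0")),
    # 8: indel (removed)
    site("geneE", 9, "AT", "A", 180, c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0", "41,0", "0,39", "0,42", "20,20", "21,19", "22,18")),
    # 9: all genotypes missing (removed: uncalled)
    site("geneE", 13, "C", "G", 140, rep(NA_character_, 7), rep(NA_character_, 7)),
    # 10: low depth in every hybrid (removed by depth screen)
    site("geneF", 30, "T", "A", 95, c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0", "41,0", "0,39", "0,42", "5,4", "4,5", "6,3")),
    # 11: depth 9,200 - fails "each" reading, passes "both" reading
    site("geneF", 40, "C", "A", 96, c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0", "41,0", "0,39", "0,42", "9,200", "8,150", "9,180")),
    # 12: one parent_A heterozygous (not fixed)
    site("geneG", 7, "A", "T", 130, c(hom0, het, hom1, hom1, het, het, het),
         c("40,0", "22,18", "0,39", "0,42", "20,20", "21,19", "22,18")),
    # 13: parents homozygous for the same allele (not fixed)
    site("geneG", 14, "G", "C", 130, c(hom0, hom0, hom0, hom0, het, het, het),
         c("40,0", "42,0", "39,0", "41,0", "20,20", "21,19", "22,18")),
    # 14: missing parental genotype (not fixed)
    site("geneG", 21, "T", "G", 130, c(hom0, NA, hom1, hom1, het, het, het),
         c("40,0", NA, "0,39", "0,42", "20,20", "21,19", "22,18")),
    # 15: parent_B heterozygous (not fixed)
    site("geneH", 11, "C", "T", 125, c(hom0, hom0, het, hom1, het, het, het),
         c("40,0", "42,0", "18,20", "0,42", "20,20", "21,19", "22,18")),
    # 16: clean fixed SNP on geneH
    site("geneH", 22, "A", "G", 101, c(hom0, hom0, hom1, hom1, het, het, het),
         c("35,0", "37,0", "0,36", "0,38", "55,45", "57,43", "52,48")),
    # 17: hybrid missing AD but called GT (observation dropped, site kept
    #     through the other hybrids)
    site("geneI", 6, "G", "A", 105, c(hom0, hom0, hom1, hom1, het, het, het),
         c("35,0", "37,0", "0,36", "0,38", NA, "57,43", "52,48")),
    # 18: only one hybrid passes depth (site retained)
    site("geneI", 18, "T", "C", 107, c(hom0, hom0, hom1, hom1, het, het, het),
         c("35,0", "37,0", "0,36", "0,38", "3,2", "4,4", "52,48")),
    # 19: low QUAL and multiallelic (removed twice over)
    site("geneJ", 4, "G", c("A", "C"), 50,
         c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0,0", "41,0,0", "0,39,0", "0,42,0", "20,20,0", "21,19,0", "22,18,0")),
    # 20: zero-depth hybrid observations (skipped individuals)
    site("geneJ", 25, "A", "T", 99, c(hom0, hom0, hom1, hom1, het, het, het),
         c("40,0", "41,0", "0,39", "0,42", "0,0", "0,0", "30,10")))

  vs <- variant_set(
    chrom = vapply(sites, `[[`, "", "chrom"),
    pos = vapply(sites, function(s) as.integer(s$pos), 0L),
    ref = vapply(sites, `[[`, "", "ref"),
    alt = lapply(sites, `[[`, "alt"),
    qual = vapply(sites, function(s) as.numeric(s$qual), 0),
    gt = do.call(rbind, lapply(sites, `[[`, "gt")),
    ad = do.call(rbind, lapply(sites, `[[`, "ad")),
    samples = samples$sample_id)
  list(variants = vs, samples = samples)
}

# Independent brute-force application of the biallelic -> quality -> fixed
# rules, written directly from their definitions (no package filter calls).
brute_force_fixed <- function(vs, samples, qual_min = 70, depth_min = 10,
                              depth_rule = "each") {
  hyb <- which(samples$role == "hybrid")
  pa <- which(samples$role == "parent_A")
  pb <- which(samples$role == "parent_B")
  keep <- character(0)
  for (i in seq_len(length(vs))) {
    alt <- vs$alt[[i]]
    if (length(alt) != 1L) next
    if (nchar(vs$ref[i]) != 1L || nchar(alt) != 1L) next
    if (all(is.na(vs$gt[i, ]))) next
    if (vs$qual[i] < qual_min) next
    pass <- FALSE
    for (s in hyb) {
      d <- suppressWarnings(as.integer(strsplit(vs$ad[i, s] %||% "x", ",")[[1]]))
      if (is.na(vs$ad[i, s]) || anyNA(d)) next
      bad <- if (depth_rule == "each") any(d < depth_min) else all(d < depth_min)
      if (!bad) pass <- TRUE
    }
    if (!pass) next
    hom <- function(cols) {
      al <- unique(unlist(lapply(vs$gt[i, cols], function(g) {
        if (is.na(g)) return(NA_integer_)
        p <- as.integer(strsplit(g, "[/|]")[[1]])
        if (length(unique(p)) == 1L) p[1] else NA_integer_
      })))
      if (length(al) == 1L && !is.na(al)) al else NA_integer_
    }
    a <- hom(pa); b <- hom(pb)
    if (is.na(a) || is.na(b) || a == b) next
    keep <- c(keep, paste(vs$chrom[i], vs$pos[i]))
  }
  keep
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
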