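test_that("biallelic filter removes multiallelics, indels and uncalled sites", {
  fx <- toy_ase_fixture()
  bi <- filter_biallelic(fx$variants)
  keys <- paste(bi$chrom, bi$pos)
  expect_false("geneE 5" %in% keys)    # two ALT alleles
  expect_false("geneE 9" %in% keys)    # indel
  expect_false("geneE 13" %in% keys)   # no called genotype
  expect_true("geneA 10" %in% keys)
})

test_that("QUAL filtering is strict at 70 and depth screening is per individual", {
  fx <- toy_ase_fixture()
  suppressWarnings(fq <- filter_quality(filter_biallelic(fx$variants), fx$samples))
  keys <- paste(fq$chrom, fq$pos)
  expect_true("geneD 8" %in% keys)     # QUAL exactly 70 retained
  expect_false("geneD 16" %in% keys)   # QUAL 69 removed
  expect_false("geneF 30" %in% keys)   # all hybrids below depth 10
  # site 18 on geneI: only hybrid h3 passes; site retained, h1/h2 masked
  i <- which(fq$chrom == "geneI" & fq$pos == 18)
  expect_length(i, 1L)
  expect_true(is.na(fq$ad[i, "h1"]))
  expect_true(is.na(fq$ad[i, "h2"]))
  expect_false(is.na(fq$ad[i, "h3"]))
})

test_that("AD of (9, 200) fails the each-allele reading but passes the literal both-below reading", {
  fx <- toy_ase_fixture()
  bi <- filter_biallelic(fx$variants)
  suppressWarnings({
    each <- filter_quality(bi, fx$samples, depth_rule = "each")
    both <- filter_quality(bi, fx$samples, depth_rule = "both")
  })
  i_each <- which(each$chrom == "geneF" & each$pos == 40)
  i_both <- which(both$chrom == "geneF" & both$pos == 40)
  # under "each": every hybrid has one allele < 10, so the site disappears
  expect_length(i_each, 0L)
  # under "both": no hybrid has both alleles < 10, so all observations stand
  expect_length(i_both, 1L)
  expect_false(anyNA(both$ad[i_both, c("h1", "h2", "h3")]))
  # AD (9, 9) would fail either reading
  expect_true(all(c(9, 9) < 10))
})

test_that("missing AD under a called genotype is dropped with a warning", {
  fx <- toy_ase_fixture()
  expect_warning(filter_quality(filter_biallelic(fx$variants), fx$samples),
                 "lacked AD")
})

test_that("fixed-SNP identification requires opposite parental homozygotes", {
  fx <- toy_ase_fixture()
  suppressWarnings({
    fq <- filter_quality(filter_biallelic(fx$variants), fx$samples)
  })
  fixed <- identify_fixed_snps(fq, fx$samples)
  keys <- paste(fixed$gene_id, fixed$pos)
  expect_true(all(c("geneA 10", "geneA 20", "geneB 15") %in% keys))
  expect_false("geneG 7" %in% keys)    # a parent_A heterozygote
  expect_false("geneG 14" %in% keys)   # same allele in both parents
  expect_false("geneG 21" %in% keys)   # missing parental genotype
  expect_false("geneH 11" %in% keys)   # a parent_B heterozygote
  # orientation: com allele recorded whether REF or ALT
  a10 <- fixed[fixed$gene_id == "geneA" & fixed$pos == 10, ]
  expect_equal(a10$allele_A, "A"); expect_equal(a10$a_index, 0L)
  c12 <- fixed[fixed$gene_id == "geneC" & fixed$pos == 12, ]
  expect_equal(c12$allele_A, "C"); expect_equal(c12$a_index, 1L)
  no_parents <- fx$samples[fx$samples$role == "hybrid", ]
  vs_h <- fq
  vs_h$gt <- fq$gt[, no_parents$sample_id, drop = FALSE]
  vs_h$ad <- fq$ad[, no_parents$sample_id, drop = FALSE]
  vs_h$samples <- no_parents$sample_id
  expect_error(identify_fixed_snps(vs_h, no_parents),
               class = "electroase_validation_error")
})

test_that("per-individual proportions average over SNPs, not pooled reads", {
  samples <- data.frame(
    sample_id = c("pa", "pb", "h1"), cohort = c("com", "tsh", "com_x_tsh"),
    tissue = "EO", duration_ms = c(0.4, 5, 0.4), replicate = 1L,
    role = c("parent_A", "parent_B", "hybrid"), stringsAsFactors = FALSE)
  vs <- variant_set(
    chrom = c("g1", "g1", "g2", "g3"), pos = c(10L, 20L, 10L, 10L),
    ref = c("A", "C", "G", "T"), alt = list("G", "T", "A", "C"),
    qual = rep(100, 4),
    gt = rbind(c("0/0", "1/1", "0/1"), c("0/0", "1/1", "0/1"),
               c("0/0", "1/1", "0/1"), c("0/0", "1/1", "0/1")),
    ad = rbind(c("50,0", "0,50", "10,40"),   # p = 0.2
               c("50,0", "0,50", "40,60"),   # p = 0.4
               c("50,0", "0,50", "30,0"),    # p = 1.0
               c("50,0", "0,50", "25,25")),  # p = 0.5
    samples = samples$sample_id)
  fixed <- identify_fixed_snps(vs, samples)
  obs <- allelic_proportions(fixed, vs, samples, "com_x_tsh")
  g1 <- obs[obs$gene_id == "g1", ]
  expect_equal(g1$proportion_A, 0.3)            # mean(0.2, 0.4)
  expect_equal(g1$reads_A, 50L)                 # 10 + 40 summed for reporting
  expect_equal(g1$reads_B, 100L)
  pooled <- allelic_proportions(fixed, vs, samples, "com_x_tsh",
                                aggregate = "pooled")
  expect_equal(pooled[pooled$gene_id == "g1", "proportion_A"], 50 / 150)
  expect_equal(obs[obs$gene_id == "g2", "proportion_A"], 1.0)
  expect_equal(obs[obs$gene_id == "g3", "proportion_A"], 0.5)
})

test_that("zero-depth SNPs are skipped per individual", {
  samples <- data.frame(
    sample_id = c("pa", "pb", "h1"), cohort = c("com", "tsh", "com_x_tsh"),
    tissue = "EO", duration_ms = c(0.4, 5, 0.4), replicate = 1L,
    role = c("parent_A", "parent_B", "hybrid"), stringsAsFactors = FALSE)
  vs <- variant_set(
    chrom = c("g1", "g1"), pos = c(10L, 20L), ref = c("A", "C"),
    alt = list("G", "T"), qual = c(100, 100),
    gt = rbind(c("0/0", "1/1", "0/1"), c("0/0", "1/1", "0/1")),
    ad = rbind(c("50,0", "0,50", "0,0"), c("50,0", "0,50", "30,10")),
    samples = samples$sample_id)
  fixed <- identify_fixed_snps(vs, samples)
  obs <- allelic_proportions(fixed, vs, samples, "com_x_tsh")
  expect_equal(obs$n_snps, 1L)
  expect_equal(obs$proportion_A, 0.75)
})

test_that("AEI classification applies both rules with strict bounds", {
  obs <- function(gene, props) data.frame(
    gene_id = gene, sample_id = sprintf("h%d", seq_along(props)),
    cohort = "com_x_rhy", tissue = "EO", n_snps = 1L,
    reads_A = 10L, reads_B = 10L, proportion_A = props,
    stringsAsFactors = FALSE)
  calls <- classify_aei(rbind(
    obs("kcnj2_like", c(0.15, 0.17, 0.16)),     # mean 0.16: B-biased
    obs("balanced", c(0.48, 0.52, 0.50)),
    obs("scn4aa_like", c(0.64, 0.68, 0.66)),    # mean 0.66: A-biased
    obs("at_bound", c(0.6, 0.6, 0.6)),          # mean exactly 0.6: balanced
    obs("mixed", c(0.65, 0.55, 0.75))))         # mean 0.65 but one <= 0.6
  row <- function(g) calls[calls$gene_id == g, ]
  expect_true(row("kcnj2_like")$imbalanced_mean_rule)
  expect_equal(row("kcnj2_like")$direction, "B_biased")
  expect_true(row("kcnj2_like")$imbalanced_all_individuals_rule)
  expect_false(row("balanced")$imbalanced_mean_rule)
  expect_equal(row("balanced")$direction, "balanced")
  expect_true(row("scn4aa_like")$imbalanced_mean_rule)
  expect_equal(row("scn4aa_like")$direction, "A_biased")
  expect_false(row("at_bound")$imbalanced_mean_rule)
  expect_equal(row("at_bound")$direction, "balanced")
  expect_true(row("mixed")$imbalanced_mean_rule)
  expect_false(row("mixed")$imbalanced_all_individuals_rule)
  # CI is Student-t on individual proportions and brackets the mean
  b <- row("balanced")
  expect_true(b$ci_low <= b$mean_proportion_A &&
                b$mean_proportion_A <= b$ci_high)
  p <- c(0.48, 0.52, 0.50)
  expect_equal(b$ci_low, mean(p) - qt(0.975, 2) * sd(p) / sqrt(3),
               tolerance = 1e-12)
  single <- classify_aei(obs("lonely", 0.9))
  expect_true(is.na(single$ci_low) && is.na(single$ci_high))
  expect_equal(single$n_individuals, 1L)
})

test_that("proportions are invariant to REF/ALT orientation", {
  fx <- toy_ase_fixture()
  suppressWarnings(fq <- filter_quality(filter_biallelic(fx$variants), fx$samples))
  fixed <- identify_fixed_snps(fq, fx$samples)
  obs <- allelic_proportions(fixed, fq, fx$samples, "com_x_tsh")

  # swap REF/ALT everywhere: flip genotype indices and reverse AD order
  swap <- fq
  flip_gt <- function(g) {
    if (is.na(g)) return(NA_character_)
    paste(vapply(strsplit(g, "/")[[1]],
                 function(tok) if (tok == ".") "." else as.character(1L - as.integer(tok)),
                 ""), collapse = "/")
  }
  flip_ad <- function(a) {
    if (is.na(a)) return(NA_character_)
    paste(rev(strsplit(a, ",")[[1]]), collapse = ",")
  }
  new_ref <- vapply(swap$alt, `[[`, "", 1L)
  swap$alt <- as.list(swap$ref)
  swap$ref <- new_ref
  swap$gt <- matrix(vapply(swap$gt, flip_gt, ""), nrow = nrow(swap$gt),
                    dimnames = dimnames(swap$gt))
  swap$ad <- matrix(vapply(swap$ad, flip_ad, ""), nrow = nrow(swap$ad),
                    dimnames = dimnames(swap$ad))
  fixed_sw <- identify_fixed_snps(swap, fx$samples)
  obs_sw <- allelic_proportions(fixed_sw, swap, fx$samples, "com_x_tsh")
  m <- merge(obs, obs_sw, by = c("gene_id", "sample_id"))
  expect_gt(nrow(m), 0L)
  expect_equal(m$proportion_A.x, m$proportion_A.y, tolerance = 1e-12)
  expect_equal(fixed$allele_A[order(paste(fixed$gene_id, fixed$pos))],
               fixed_sw$allele_A[order(paste(fixed_sw$gene_id, fixed_sw$pos))])
})

test_that("the filter chain is order-robust", {
  fx <- toy_ase_fixture()
  suppressWarnings({
    ab <- identify_fixed_snps(
      filter_quality(filter_biallelic(fx$variants), fx$samples), fx$samples)
    ba <- identify_fixed_snps(
      filter_biallelic(filter_quality(fx$variants, fx$samples)), fx$samples)
  })
  expect_identical(paste(ab$gene_id, ab$pos, ab$allele_A),
                   paste(ba$gene_id, ba$pos, ba$allele_A))
})

test_that("observation read sums equal the AD sums in the variant set", {
  cfg <- sim_config(n_genes = 40, n_aei_genes = 4, n_ase_background_genes = 6,
                    decoy_fraction = 0, seed = 23)
  sim <- simulate_experiment(cfg)
  vs <- simulate_allelic_reads(cfg, sim$truth)
  fq <- filter_quality(filter_biallelic(vs), sim$samples)
  fixed <- identify_fixed_snps(fq, sim$samples,
                               parent_a_cohort = "com", parent_b_cohort = "tsh")
  obs <- allelic_proportions(fixed, fq, sim$samples, "com_x_tsh", tissue = "EO")
  for (r in seq_len(nrow(obs))) {
    snp_rows <- fixed[fixed$gene_id == obs$gene_id[r], ]
    total <- 0L
    for (k in seq_len(nrow(snp_rows))) {
      i <- which(fq$chrom == snp_rows$gene_id[k] & fq$pos == snp_rows$pos[k])
      d <- ad_depths(fq$ad[i, obs$sample_id[r]])
      if (!is.null(d)) total <- total + sum(d)
    }
    expect_equal(obs$reads_A[r] + obs$reads_B[r], total)
  }
})

test_that("protein-allele comparison reports non-synonymous sites only", {
  skip_if_not_installed("seqinr")
  base <- paste(rep("GCT", 200), collapse = "")   # 200 alanines
  expect_equal(nrow(compare_protein_alleles(base, base)), 0L)

  synonymous <- paste0(substr(base, 1, 177), "GCC", substr(base, 181, 600))
  expect_equal(nrow(compare_protein_alleles(base, synonymous)), 0L)

  # codon 60 GCT -> GTT changes Ala to Val
  mutated <- paste0(substr(base, 1, 177), "GTT", substr(base, 181, 600))
  subs <- compare_protein_alleles(base, mutated)
  expect_equal(nrow(subs), 1L)
  expect_equal(subs$site, 60L)
  # independent oracle: translate both with seqinr's codon tables
  aa_a <- seqinr::translate(strsplit(base, "")[[1]])
  aa_b <- seqinr::translate(strsplit(mutated, "")[[1]])
  expect_equal(which(aa_a != aa_b), 60L)
  expect_equal(subs$residue_a, aa_a[60])
  expect_equal(subs$residue_b, aa_b[60])
})

test_that("protein comparison validates frame, length and internal stops", {
  base <- paste(rep("GCT", 10), collapse = "")
  expect_error(compare_protein_alleles(base, paste0(base, "GCT")),
               class = "electroase_validation_error")
  expect_error(compare_protein_alleles(substr(base, 1, 29), substr(base, 1, 29)),
               class = "electroase_validation_error")
  internal_stop <- paste0("TAA", substr(base, 4, 30))
  expect_error(compare_protein_alleles(internal_stop, substr(base, 1, 30)),
               class = "electroase_validation_error")
  # trailing stop in both alleles is tolerated
  ok <- paste0(base, "TAA")
  expect_equal(nrow(compare_protein_alleles(ok, ok)), 0L)
})
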