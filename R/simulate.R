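#' Configuration for the synthetic experiment generator
#'
#' Defaults emulate the study design the pipeline targets: three purebred
#' cohorts with short (0.4 ms), medium (5 ms) and long (40 ms) EOD durations
#' (5, 3 and 5 replicates respectively), and two hybrid cohorts of 5
#' replicates each, every cohort sampled in both tissues (EO and SM). Planted
#' structure: a fraction of genes with an EO-vs-SM log2 effect, a fraction
#' with an EO-specific expression slope along log10 EOD duration (these also
#' receive an EO-upregulation of `duration_tissue_lfc` so they are
#' EO-specific, as the pattern-selection criteria require), and a set of
#' genes with allele-specific expression at fixed parental SNPs in hybrids.
#'
#' @param n_genes Number of genes to simulate.
#' @param cohorts `data.frame` with columns `name`, `duration_ms`,
#'   `n_replicates`, `is_hybrid`, `role` (one row per cohort).
#' @param baseline_log_mean Mean of the per-gene baseline log2 expression.
#' @param baseline_log_sd Spread (sd, log2 scale) of per-gene baselines.
#' @param dispersion NB dispersion: scalar or per-gene vector. Variance of a
#'   count with mean `mu` is `mu + dispersion * mu^2`.
#' @param frac_tissue_de Fraction of genes with a planted tissue effect.
#' @param tissue_lfc Magnitude (log2) of the planted EO-vs-SM effect; sign is
#'   random per gene.
#' @param frac_duration_genes Fraction of genes whose EO expression tracks
#'   EOD duration.
#' @param duration_slope_log2 Planted EO slope, log2 units per log10 ms.
#' @param duration_tissue_lfc EO-upregulation (log2) given to duration genes.
#' @param n_aei_genes Number of genes with planted allelic imbalance.
#' @param aei_proportions True com-allele proportions, recycled over the AEI
#'   genes; values in (0, 1].
#' @param n_ase_background_genes Genes with balanced (0.5) allelic expression.
#' @param snps_per_gene Fixed parental SNPs simulated per ASE gene.
#' @param snp_depth_mean Mean sequencing depth per SNP (Poisson).
#' @param qual_range Range from which passing site QUAL values are drawn.
#' @param decoy_fraction Fraction of additional decoy sites (multiallelic,
#'   indel, low-QUAL, low-depth, non-fixed) emitted to exercise the filters.
#' @param library_size_factors Optional per-sample size factors; drawn
#'   log-normally (sd 0.15) when `NULL`.
#' @param seed Integer seed governing all randomness; per-gene substreams are
#'   derived from it so truth assignments are stable when genes are added.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       cohorts = default_cohorts(),
                       baseline_log_mean = log2(500),
                       baseline_log_sd = 1.5,
                       dispersion = 0.05,
                       frac_tissue_de = 0.1,
                       tissue_lfc = 2,
                       frac_duration_genes = 0.05,
                       duration_slope_log2 = 1,
                       duration_tissue_lfc = 2.5,
                       n_aei_genes = 8,
                       aei_proportions = c(0.16, 0.2, 0.8, 0.86),
                       n_ase_background_genes = 100,
                       snps_per_gene = 3,
                       snp_depth_mean = 100,
                       qual_range = c(80, 200),
                       decoy_fraction = 0.2,
                       library_size_factors = NULL,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_cohorts <- function() {
  data.frame(
    name = c("com", "tsh", "rhy", "com_x_tsh", "com_x_rhy"),
    duration_ms = c(0.4, 5, 40, 0.4, 4),
    n_replicates = c(5L, 3L, 5L, 5L, 5L),
    is_hybrid = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    role = c("parent_A", "parent_B", "parent_B", "hybrid", "hybrid"),
    stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is.numeric(n_genes) || n_genes < 1 || n_genes != round(n_genes))
      stop_validation("n_genes must be a positive integer")
    need <- c("name", "duration_ms", "n_replicates", "is_hybrid", "role")
    if (!is.data.frame(cohorts) || !all(need %in% names(cohorts)) ||
        nrow(cohorts) == 0L)
      stop_validation("cohorts must be a data.frame with columns %s",
                      paste(need, collapse = ", "))
    if (any(cohorts$duration_ms <= 0) || any(cohorts$n_replicates < 1))
      stop_validation("cohort durations and replicate numbers must be positive")
    for (f in c("frac_tissue_de", "frac_duration_genes", "decoy_fraction"))
      if (get(f) < 0 || get(f) > 1)
        stop_validation("%s must lie in [0, 1]", f)
    if (any(dispersion <= 0)) stop_validation("dispersion must be positive")
    if (!(length(dispersion) %in% c(1L, n_genes)))
      stop_validation("dispersion must be scalar or one value per gene")
    if (n_aei_genes > 0 && length(aei_proportions) < 1L)
      stop_validation("aei_proportions must be non-empty when n_aei_genes > 0")
    if (length(aei_proportions) > 0 &&
        (any(aei_proportions <= 0) || any(aei_proportions > 1)))
      stop_validation("aei_proportions must lie in (0, 1]")
    if (snps_per_gene < 1 || snp_depth_mean <= 0)
      stop_validation("snps_per_gene and snp_depth_mean must be positive")
    if (length(qual_range) != 2L || qual_range[1] > qual_range[2])
      stop_validation("qual_range must be an ascending pair")
    if (!is.null(library_size_factors) && any(library_size_factors <= 0))
      stop_validation("library_size_factors must be positive")
  })
  cfg
}

# Deterministic per-gene substream seed: stable under edits that add genes.
gene_seed <- function(seed, g, stream = 0L) {
  (((seed %% 65011) + 1) * 20011 + g * 997 + stream * 104729) %% 2147483629
}

build_sample_sheet <- function(cfg) {
  rows <- do.call(rbind, lapply(seq_len(nrow(cfg$cohorts)), function(i) {
    co <- cfg$cohorts[i, ]
    expand.grid(replicate = seq_len(co$n_replicates), tissue = c("EO", "SM"),
                stringsAsFactors = FALSE)[, 2:1] |>
      transform(cohort = co$name, duration_ms = co$duration_ms, role = co$role)
  }))
  rows$sample_id <- sprintf("%s_%s_%d", rows$cohort, rows$tissue, rows$replicate)
  validate_sample_sheet(rows[, c("sample_id", "cohort", "tissue",
                                 "duration_ms", "replicate", "role")])
}

#' Simulate a full expression experiment
#'
#' Draws gene-wise negative-binomial counts with mean
#' `baseline x size factor x 2^(tissue effect) x 2^(duration effect)`, where
#' the tissue effect applies to planted DE genes in EO samples and the
#' duration effect applies, in EO only, to planted duration genes as
#' `slope x (log10 duration - log10 shortest purebred duration)`. Identical
#' configuration (including seed) gives identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (integer matrix), `samples` (sample sheet)
#'   and `truth` — the planted structure: `de_genes` (gene_id, lfc),
#'   `duration_genes` (gene_id, direction), `aei_genes` (gene_id,
#'   proportion), `ase_background_genes`, and `size_factors`.
#' @export
simulate_experiment <- function(config) {
  cfg <- validate_sim_config(config)
  samples <- build_sample_sheet(cfg)
  n_samp <- nrow(samples)
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  disp <- rep_len(cfg$dispersion, cfg$n_genes)

  if (is.null(cfg$library_size_factors)) {
    set.seed(gene_seed(cfg$seed, 0L, stream = 9L))
    sf <- exp(stats::rnorm(n_samp, 0, 0.15))
    sf <- sf / exp(mean(log(sf)))
  } else {
    sf <- rep_len(cfg$library_size_factors, n_samp)
  }
  names(sf) <- samples$sample_id

  d_min <- min(cfg$cohorts$duration_ms[!cfg$cohorts$is_hybrid])
  dur_covariate <- log10(samples$duration_ms) - log10(d_min)
  is_eo <- samples$tissue == "EO"

  counts <- matrix(0L, cfg$n_genes, n_samp,
                   dimnames = list(gene_ids, samples$sample_id))
  class_lab <- character(cfg$n_genes)
  de_lfc <- numeric(0); de_id <- character(0)
  dur_dir <- character(0); dur_id <- character(0)

  for (g in seq_len(cfg$n_genes)) {
    set.seed(gene_seed(cfg$seed, g))
    u <- stats::runif(1)
    base_dev <- stats::rnorm(1)
    sgn <- if (stats::runif(1) < 0.5) 1 else -1
    mu0 <- 2^(cfg$baseline_log_mean + cfg$baseline_log_sd * base_dev)
    lfc <- 0; slope <- 0
    if (u < cfg$frac_duration_genes) {
      class_lab[g] <- "duration"
      lfc <- cfg$duration_tissue_lfc
      slope <- sgn * cfg$duration_slope_log2
      dur_id <- c(dur_id, gene_ids[g])
      dur_dir <- c(dur_dir, if (sgn > 0) "increasing" else "decreasing")
    } else if (u < cfg$frac_duration_genes + cfg$frac_tissue_de) {
      class_lab[g] <- "tissue_de"
      lfc <- sgn * cfg$tissue_lfc
      de_id <- c(de_id, gene_ids[g])
      de_lfc <- c(de_lfc, lfc)
    }
    mu <- mu0 * sf * 2^(lfc * is_eo) * 2^(slope * dur_covariate * is_eo)
    counts[g, ] <- stats::rnbinom(n_samp, mu = mu, size = 1 / disp[g])
  }

  n_ase <- min(cfg$n_aei_genes + cfg$n_ase_background_genes, cfg$n_genes)
  aei_ids <- gene_ids[seq_len(min(cfg$n_aei_genes, cfg$n_genes))]
  bg_ids <- setdiff(gene_ids[seq_len(n_ase)], aei_ids)
  truth <- list(
    de_genes = data.frame(gene_id = de_id, lfc = de_lfc,
                          stringsAsFactors = FALSE),
    duration_genes = data.frame(gene_id = dur_id, direction = dur_dir,
                                stringsAsFactors = FALSE),
    aei_genes = data.frame(
      gene_id = aei_ids,
      proportion = rep_len(cfg$aei_proportions, length(aei_ids)),
      stringsAsFactors = FALSE),
    ase_background_genes = bg_ids,
    size_factors = sf)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate hybrid allele-specific read counts
#'
#' Emits a multi-sample [variant_set()] with `snps_per_gene` fixed parental
#' biallelic SNPs for every AEI and background gene in `truth`: parental
#' samples are homozygous for opposite alleles (the com allele is randomly
#' REF or ALT per site), hybrids are heterozygous with com-allele read counts
#' drawn Binomial(depth, true proportion) and total depth Poisson
#' (`snp_depth_mean`); background genes use proportion 0.5. A
#' `decoy_fraction` of extra sites (triallelic, indel, low-QUAL, low-depth,
#' non-fixed) exercises the downstream filters; the per-site kind is attached
#' as attribute `"site_info"`.
#'
#' @param config The [sim_config()] used for [simulate_experiment()].
#' @param truth The `truth` component returned by [simulate_experiment()].
#' @return A [variant_set()] covering every sample in the design.
#' @export
simulate_allelic_reads <- function(config, truth) {
  cfg <- validate_sim_config(config)
  samples <- build_sample_sheet(cfg)
  if (!any(cfg$cohorts$is_hybrid))
    stop_validation("simulate_allelic_reads requires at least one hybrid cohort")
  genes <- rbind(truth$aei_genes,
                 data.frame(gene_id = truth$ase_background_genes,
                            proportion = rep(0.5, length(truth$ase_background_genes)),
                            stringsAsFactors = FALSE))
  if (nrow(genes) == 0L)
    return(variant_set(character(), integer(), character(), list(), numeric(),
                       matrix(character(), 0, nrow(samples)),
                       matrix(character(), 0, nrow(samples)),
                       samples$sample_id))
  role <- samples$role
  nucs <- c("A", "C", "G", "T")
  rows <- list()

  emit_fixed <- function(p, qual, depth_mean, nonfixed_idx = NA) {
    ref <- sample(nucs, 1L)
    alt <- sample(setdiff(nucs, ref), 1L)
    com_is_ref <- stats::runif(1) < 0.5
    com_idx <- if (com_is_ref) 0L else 1L
    gt <- character(length(role)); ad <- character(length(role))
    for (s in seq_along(role)) {
      if (role[s] == "hybrid") {
        n <- stats::rpois(1, depth_mean)
        k_com <- stats::rbinom(1, n, p)
        dref <- if (com_is_ref) k_com else n - k_com
        gt[s] <- "0/1"; ad[s] <- paste(dref, n - dref, sep = ",")
      } else {
        hom <- if (role[s] == "parent_A") com_idx
               else if (role[s] == "parent_B") 1L - com_idx else 0L
        n <- stats::rpois(1, depth_mean)
        gt[s] <- paste(hom, hom, sep = "/")
        ad[s] <- if (hom == 0L) paste(n, 0, sep = ",") else paste(0, n, sep = ",")
      }
    }
    if (!is.na(nonfixed_idx)) {  # corrupt one parent_A genotype
      gt[nonfixed_idx] <- "0/1"
      n <- stats::rpois(1, depth_mean)
      ad[nonfixed_idx] <- paste(ceiling(n / 2), floor(n / 2), sep = ",")
    }
    list(ref = ref, alt = list(alt), qual = qual, gt = gt, ad = ad)
  }

  decoy_kinds <- c("triallelic", "indel", "low_qual", "low_depth", "non_fixed")
  n_main <- nrow(genes) * cfg$snps_per_gene
  n_decoy <- round(cfg$decoy_fraction * n_main)
  decoy_gene <- rep_len(genes$gene_id, n_decoy)
  decoy_kind <- rep_len(decoy_kinds, n_decoy)

  for (gi in seq_len(nrow(genes))) {
    g_idx <- as.integer(sub("gene", "", genes$gene_id[gi]))
    set.seed(gene_seed(cfg$seed, g_idx, stream = 3L))
    p <- genes$proportion[gi]
    for (j in seq_len(cfg$snps_per_gene)) {
      site <- emit_fixed(p, stats::runif(1, cfg$qual_range[1], cfg$qual_range[2]),
                         cfg$snp_depth_mean)
      rows[[length(rows) + 1L]] <- c(
        list(chrom = genes$gene_id[gi], pos = 50L * j, kind = "fixed"), site)
    }
    # decoys assigned to this gene, drawn inside its substream
    for (k in which(decoy_gene == genes$gene_id[gi])) {
      kind <- decoy_kind[k]
      pos <- 10000L + k
      qual <- stats::runif(1, cfg$qual_range[1], cfg$qual_range[2])
      site <- switch(kind,
        triallelic = {
          s <- emit_fixed(p, qual, cfg$snp_depth_mean)
          s$alt <- list(c(s$alt[[1L]],
                          setdiff(nucs, c(s$ref, s$alt[[1L]]))[1L]))
          s$ad <- paste(s$ad, "0", sep = ",")
          s
        },
        indel = {
          s <- emit_fixed(p, qual, cfg$snp_depth_mean)
          s$ref <- paste0(s$ref, "T")
          s
        },
        low_qual = emit_fixed(p, stats::runif(1, 30, 69.5), cfg$snp_depth_mean),
        low_depth = emit_fixed(p, qual, 8),
        non_fixed = emit_fixed(p, qual, cfg$snp_depth_mean,
                               nonfixed_idx = which(role == "parent_A")[1L]))
      rows[[length(rows) + 1L]] <- c(
        list(chrom = genes$gene_id[gi], pos = pos, kind = kind), site)
    }
  }

  ord <- order(vapply(rows, `[[`, "", "chrom"),
               vapply(rows, `[[`, 0L, "pos"))
  rows <- rows[ord]
  vs <- variant_set(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = lapply(rows, `[[`, "alt") |> lapply(`[[`, 1L),
    qual = vapply(rows, `[[`, 0, "qual"),
    gt = do.call(rbind, lapply(rows, `[[`, "gt")),
    ad = do.call(rbind, lapply(rows, `[[`, "ad")),
    samples = samples$sample_id)
  attr(vs, "site_info") <- data.frame(
    gene_id = vs$chrom, pos = vs$pos,
    kind = vapply(rows, `[[`, "", "kind"), stringsAsFactors = FALSE)
  vs
}

#' Simulate a two-group null count matrix
#'
#' Calibration harness: NB counts with identical means in both groups, used
#' to measure the type-I error of the tissue Wald test.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group (>= 2).
#' @param dispersion NB dispersion shared by all genes.
#' @param seed Integer seed.
#' @param mean Common NB mean (default 100).
#' @return Integer count matrix; columns `A_*` then `B_*`.
#' @export
simulate_null_counts <- function(n_genes, n_per_group, dispersion, seed,
                                 mean = 100) {
  if (n_per_group < 2) stop_validation("n_per_group must be >= 2")
  if (dispersion <= 0) stop_validation("dispersion must be positive")
  set.seed(seed)
  n <- 2L * n_per_group
  m <- matrix(stats::rnbinom(n_genes * n, mu = mean, size = 1 / dispersion),
              nrow = n_genes,
              dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                              c(sprintf("A_%d", seq_len(n_per_group)),
                                sprintf("B_%d", seq_len(n_per_group)))))
  storage.mode(m) <- "integer"
  m
}
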