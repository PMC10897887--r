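#' Pipeline configuration
#'
#' Collects the input paths, stage toggles, thresholds and mode switches of a
#' full run. Threshold defaults are the study values: DEG rule |log2FC| > 1
#' at adjusted p < 0.05, site QUAL >= 70, allelic depth >= 10, allelic
#' imbalance outside (0.4, 0.6).
#'
#' @param counts,samples,vcf Input paths (the VCF may be `NULL` when the ASE
#'   stage is disabled).
#' @param outdir Output directory (created if needed).
#' @param de,duration,ase Stage toggles.
#' @param lfc_threshold,alpha,qual_min,depth_min,aei_low,aei_high,cluster_correlation_cut
#'   Analysis thresholds.
#' @param use_adjusted_p Adjusted-p (default) vs raw-p DEG calling.
#' @param duration_as_factor Duration as design factor (default) vs
#'   continuous log10(ms).
#' @param depth_rule AD filter reading, `"each"` or `"both"`; see
#'   [filter_quality()].
#' @param snp_aggregate Per-individual SNP aggregation, `"mean"` or
#'   `"pooled"`; see [allelic_proportions()].
#' @param hybrid_sets Optional `data.frame` with columns `hybrid`,
#'   `parent_a`, `parent_b` naming the cohorts of each hybrid set; by default
#'   hybrid cohort names of the form `a_x_b` are split on `"_x_"`.
#' @param seed Integer seed recorded in the run report.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples, vcf = NULL, outdir,
                            de = TRUE, duration = TRUE, ase = TRUE,
                            lfc_threshold = 1, alpha = 0.05,
                            qual_min = 70, depth_min = 10,
                            aei_low = 0.4, aei_high = 0.6,
                            cluster_correlation_cut = 0.7,
                            use_adjusted_p = TRUE,
                            duration_as_factor = TRUE,
                            depth_rule = "each",
                            snp_aggregate = "mean",
                            hybrid_sets = NULL,
                            seed = 1) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (!(cfg$aei_low < 0.5 && 0.5 < cfg$aei_high))
    stop_validation("aei bounds must satisfy aei_low < 0.5 < aei_high")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop_validation("alpha must lie in (0, 1)")
  if (cfg$lfc_threshold <= 0 || cfg$qual_min < 0 || cfg$depth_min < 0)
    stop_validation("thresholds must be positive")
  if (cfg$cluster_correlation_cut <= 0 || cfg$cluster_correlation_cut > 1)
    stop_validation("cluster_correlation_cut must lie in (0, 1]")
  cfg$depth_rule <- match.arg(cfg$depth_rule, c("each", "both"))
  cfg$snp_aggregate <- match.arg(cfg$snp_aggregate, c("mean", "pooled"))
  cfg
}

# Hash of the analysis parameters only: file-system locations are excluded
# so the same analysis in a different directory hashes identically.
config_hash <- function(cfg) {
  keep <- setdiff(names(cfg), c("counts", "samples", "vcf", "outdir"))
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg[keep], auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

write_result_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# electroase %s config_hash=%s",
                     as.character(utils::packageVersion("electroase")), hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

hybrid_sets_from_names <- function(samples) {
  hyb <- unique(samples$cohort[samples$role == "hybrid"])
  sets <- lapply(hyb, function(h) {
    parts <- strsplit(h, "_x_", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop_validation("cannot infer parents of hybrid cohort '%s'; supply hybrid_sets", h)
    data.frame(hybrid = h, parent_a = parts[1L], parent_b = parts[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, sets)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages on the configured inputs, writes one TSV per
#' result (each carrying the configuration hash in a `#` header comment),
#' and a machine-readable `run_report.json` with package version, seed,
#' configuration hash and per-stage summary counts. A given configuration
#' and input always produce identical outputs.
#'
#' Stages: `de` — per-cohort EO-vs-SM Wald tests, DEG calls and the shared
#' up/down intersections; `duration` — purebred interaction LRT, pattern
#' clustering of significant genes and selection of monotone EO-specific
#' groups; `ase` — biallelic/quality filtering, fixed parental SNPs per
#' hybrid set, per-individual proportions and AEI calls per tissue.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  report <- list(package = "electroase",
                 version = as.character(utils::packageVersion("electroase")),
                 seed = config$seed, config_hash = hash, stages = list())

  samples <- read_sample_sheet(config$samples)
  counts <- read_count_matrix(config$counts)
  counts <- counts[, intersect(colnames(counts), samples$sample_id), drop = FALSE]
  filtered <- filter_low_expression(counts)

  if (isTRUE(config$de)) {
    cohorts <- unique(samples$cohort)
    per_cohort <- list()
    for (co in cohorts) {
      res <- wald_test_tissue(filtered, samples, co)
      write_result_tsv(res, file.path(config$outdir, sprintf("de_%s.tsv", co)), hash)
      per_cohort[[co]] <- call_degs(res, config$lfc_threshold, config$alpha,
                                    use_adjusted = config$use_adjusted_p)
    }
    shared <- shared_degs(per_cohort)
    all_ids <- sort(unique(unlist(c(shared$per_cohort_up, shared$per_cohort_down))))
    membership <- data.frame(gene_id = all_ids, stringsAsFactors = FALSE)
    for (co in cohorts) {
      membership[[paste0("up_", co)]] <- all_ids %in% shared$per_cohort_up[[co]]
      membership[[paste0("down_", co)]] <- all_ids %in% shared$per_cohort_down[[co]]
    }
    membership$up_shared <- all_ids %in% shared$up_shared
    membership$down_shared <- all_ids %in% shared$down_shared
    write_result_tsv(membership, file.path(config$outdir, "shared_degs.tsv"), hash)
    report$stages$de <- list(
      n_cohorts = length(cohorts),
      n_up_shared = length(shared$up_shared),
      n_down_shared = length(shared$down_shared),
      shared_deg_rows = nrow(membership))
  }

  if (isTRUE(config$duration)) {
    purebred <- samples[samples$role != "hybrid", , drop = FALSE]
    pb_counts <- filtered[, purebred$sample_id, drop = FALSE]
    lrt <- lrt_interaction(pb_counts, purebred,
                           duration_as_factor = config$duration_as_factor)
    write_result_tsv(lrt, file.path(config$outdir, "duration_lrt.tsv"), hash)
    sig <- lrt$gene_id[lrt$converged & !is.na(lrt$p_adj) & lrt$p_adj < config$alpha]
    groups <- cluster_patterns(pb_counts, purebred, sig,
                               cor_cut = config$cluster_correlation_cut)
    write_result_tsv(groups$membership,
                     file.path(config$outdir, "duration_groups.tsv"), hash)
    sel <- select_duration_groups(groups)
    write_result_tsv(sel$group_provenance,
                     file.path(config$outdir, "duration_selected.tsv"), hash)
    report$stages$duration <- list(
      n_significant = length(sig), n_groups = groups$n_groups,
      n_increasing = length(sel$increasing),
      n_decreasing = length(sel$decreasing),
      selected_rows = nrow(sel$group_provenance))
  }

  if (isTRUE(config$ase)) {
    if (is.null(config$vcf)) stop_validation("ase stage enabled but no VCF configured")
    vs <- read_vcf(config$vcf, samples)
    vs <- filter_quality(filter_biallelic(vs), samples,
                         qual_min = config$qual_min,
                         depth_min = config$depth_min,
                         depth_rule = config$depth_rule)
    sets <- config$hybrid_sets %||% hybrid_sets_from_names(samples)
    aei_all <- list(); fixed_all <- list(); obs_all <- list()
    for (i in seq_len(nrow(sets))) {
      set <- sets[i, ]
      fixed <- identify_fixed_snps(vs, samples,
                                   parent_a_cohort = set$parent_a,
                                   parent_b_cohort = set$parent_b)
      if (nrow(fixed) == 0L) next
      fixed_all[[set$hybrid]] <- cbind(hybrid = set$hybrid, fixed)
      for (tis in c("EO", "SM")) {
        obs <- allelic_proportions(fixed, vs, samples, set$hybrid, tissue = tis,
                                   aggregate = config$snp_aggregate)
        obs_all[[paste(set$hybrid, tis)]] <- obs
        aei_all[[paste(set$hybrid, tis)]] <-
          classify_aei(obs, low = config$aei_low, high = config$aei_high)
      }
    }
    fixed_df <- do.call(rbind, fixed_all) %||%
      data.frame(hybrid = character(), gene_id = character())
    obs_df <- do.call(rbind, obs_all) %||% data.frame(gene_id = character())
    aei_df <- do.call(rbind, aei_all) %||%
      data.frame(gene_id = character(), imbalanced_mean_rule = logical())
    rownames(fixed_df) <- rownames(obs_df) <- rownames(aei_df) <- NULL
    write_result_tsv(fixed_df, file.path(config$outdir, "ase_fixed_snps.tsv"), hash)
    write_result_tsv(obs_df, file.path(config$outdir, "ase_observations.tsv"), hash)
    write_result_tsv(aei_df, file.path(config$outdir, "ase_aei_calls.tsv"), hash)
    report$stages$ase <- list(
      n_sites_after_filters = length(vs),
      fixed_snp_rows = nrow(fixed_df),
      observation_rows = nrow(obs_df),
      aei_rows = nrow(aei_df),
      n_imbalanced_mean_rule = sum(aei_df$imbalanced_mean_rule))
  }

  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Write a complete synthetic fixture set
#'
#' Runs the generator and writes everything a pipeline run needs: the count
#' matrix, sample sheet and multi-sample VCF, plus plain-text truth tables
#' (planted DE genes, duration genes, AEI genes, size factors) for
#' parameter-recovery checks. Identical configurations produce byte-identical
#' files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixtures <- function(config, outdir) {
  cfg <- validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(cfg)
  vs <- simulate_allelic_reads(cfg, sim$truth)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             samples = file.path(outdir, "samples.tsv"),
             vcf = file.path(outdir, "variants.vcf"),
             truth_de = file.path(outdir, "truth_de_genes.tsv"),
             truth_duration = file.path(outdir, "truth_duration_genes.tsv"),
             truth_aei = file.path(outdir, "truth_aei_genes.tsv"),
             truth_size_factors = file.path(outdir, "truth_size_factors.tsv"))
  write_count_matrix(sim$counts, paths["counts"])
  write_sample_sheet(sim$samples, paths["samples"])
  write_vcf(vs, paths["vcf"])
  utils::write.table(sim$truth$de_genes, paths["truth_de"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$duration_genes, paths["truth_duration"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$aei_genes, paths["truth_aei"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$truth$size_factors),
               size_factor = unname(sim$truth$size_factors)),
    paths["truth_size_factors"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
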