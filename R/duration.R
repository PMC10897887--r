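#' Interaction likelihood-ratio test against EOD duration
#'
#' Tests, gene by gene, whether the EO-vs-SM expression contrast changes
#' with EOD duration: the full negative-binomial GLM
#' `~ duration + tissue + duration:tissue` is compared with the reduced model
#' `~ duration + tissue` by a likelihood-ratio test. Only purebred (F0)
#' cohorts may be supplied — hybrid expression would distort the duration
#' axis — and at least three distinct duration levels are required. Duration
#' enters as a factor ordered by `duration_ms` by default (with three levels
#' and two tissues the test has 2 degrees of freedom); set
#' `duration_as_factor = FALSE` for a continuous log10(ms) covariate (1 df).
#' The dispersion of each gene is estimated once under the full design and
#' shared between both fits, which guarantees a non-negative test statistic
#' for nested models.
#'
#' @param counts Integer count matrix covering the purebred samples.
#' @param samples Sample sheet rows for those samples; no `role == "hybrid"`
#'   entries allowed.
#' @param duration_as_factor Treat duration as an unordered design factor
#'   (default) or as continuous log10 milliseconds.
#' @param size_factors,dispersions Optional precomputed values.
#' @return `data.frame`: `gene_id`, `deviance_full`, `deviance_reduced`,
#'   `stat`, `df`, `p_value`, `p_adj` (BH across genes), `converged`.
#' @export
lrt_interaction <- function(counts, samples, duration_as_factor = TRUE,
                            size_factors = NULL, dispersions = NULL) {
  counts <- validate_count_matrix(counts)
  samples <- samples_for(samples, colnames(counts))
  if (any(samples$role == "hybrid"))
    stop_validation("lrt_interaction expects purebred (F0) samples only")
  durations <- sort(unique(samples$duration_ms))
  if (length(durations) < 3L)
    stop_validation("need >= 3 distinct duration levels, got %d", length(durations))
  if (length(unique(samples$tissue)) < 2L)
    stop_validation("both tissues must be present")

  sf <- size_factors %||% estimate_size_factors(counts)
  disp <- dispersions %||% estimate_dispersions(counts, samples, size_factors = sf)
  tissue <- factor(samples$tissue, levels = c("SM", "EO"))
  dur <- if (duration_as_factor) {
    factor(samples$duration_ms, levels = durations)
  } else {
    log10(samples$duration_ms)
  }
  X_full <- stats::model.matrix(~ dur * tissue)
  X_red <- stats::model.matrix(~ dur + tissue)
  df_diff <- qr(X_full)$rank - qr(X_red)$rank
  offset <- log(sf)

  n_genes <- nrow(counts)
  dev_f <- dev_r <- stat <- pval <- rep(NA_real_, n_genes)
  conv <- rep(FALSE, n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    ff <- nb_glm_fit(y, X_full, disp[g], offset)
    fr <- nb_glm_fit(y, X_red, disp[g], offset)
    if (!ff$converged || !fr$converged) next
    conv[g] <- TRUE
    dev_f[g] <- ff$deviance
    dev_r[g] <- fr$deviance
    stat[g] <- max(dev_r[g] - dev_f[g], 0)   # nested models; clamp rounding
    pval[g] <- stats::pchisq(stat[g], df = df_diff, lower.tail = FALSE)
  }
  data.frame(gene_id = rownames(counts), deviance_full = dev_f,
             deviance_reduced = dev_r, stat = stat, df = df_diff,
             p_value = pval, p_adj = stats::p.adjust(pval, method = "BH"),
             converged = conv, stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster significant genes by expression pattern
#'
#' Builds, for each significant gene, a standardized profile over the six
#' (duration, tissue) design cells — the z-score across cells of the mean
#' normalized `log2(x + 1)` expression — and groups genes by agglomerative
#' hierarchical clustering on `1 - Pearson correlation` distance with average
#' linkage. The tree is cut at height `1 - cor_cut`; under average linkage
#' every merge inside a retained group happened at a mean cross-correlation
#' of at least `cor_cut`, so each group's mean pairwise member correlation is
#' guaranteed to reach `cor_cut`, and each group collects genes following one
#' expression pattern across duration and tissue. Every significant gene is
#' assigned to exactly one group.
#'
#' @param counts Integer count matrix.
#' @param samples Sample sheet for the purebred samples in `counts`.
#' @param significant Character vector of significant gene ids (subset of
#'   `rownames(counts)`).
#' @param cor_cut Required mean within-group pairwise correlation (default
#'   0.7).
#' @param min_group_size Groups smaller than this are consolidated into the
#'   large group whose members they correlate best with (mean cross
#'   correlation of at least 0.5), mirroring how degPatterns-style
#'   clustering reattaches stragglers; unmatched small groups stay separate.
#' @param size_factors Optional size factors.
#' @return Object of class `pattern_groups`: list with `membership`
#'   (`gene_id`, `group_id`), `profiles` (`group_id`, `duration_ms`,
#'   `tissue`, `mean_z`), `n_groups`, `cor_cut`.
#' @export
cluster_patterns <- function(counts, samples, significant, cor_cut = 0.7,
                             min_group_size = 3L, size_factors = NULL) {
  counts <- validate_count_matrix(counts)
  samples <- samples_for(samples, colnames(counts))
  missing <- setdiff(significant, rownames(counts))
  if (length(missing) > 0L)
    stop_validation("significant gene(s) not in count matrix: %s",
                    paste(head(missing, 5L), collapse = ", "))
  empty <- structure(list(membership = data.frame(gene_id = character(),
                                                  group_id = integer()),
                          profiles = data.frame(group_id = integer(),
                                                duration_ms = numeric(),
                                                tissue = character(),
                                                mean_z = numeric()),
                          n_groups = 0L, cor_cut = cor_cut),
                     class = "pattern_groups")
  if (length(significant) == 0L) return(empty)

  sf <- size_factors %||% estimate_size_factors(counts)
  x <- log2(sweep(counts[significant, , drop = FALSE], 2L, sf, "/") + 1)
  cell <- interaction(samples$duration_ms, samples$tissue, drop = TRUE,
                      sep = "|")
  cell_means <- t(apply(x, 1L, function(r) tapply(r, cell, mean)))
  colnames(cell_means) <- levels(cell)
  prof <- t(apply(cell_means, 1L, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  colnames(prof) <- levels(cell)

  n <- nrow(prof)
  if (n == 1L) {
    grp <- setNames(1L, significant)
  } else {
    cmat <- suppressWarnings(stats::cor(t(prof)))
    cmat[!is.finite(cmat)] <- 0
    d <- stats::as.dist(1 - cmat)
    hc <- stats::hclust(d, method = "average")
    grp <- stats::cutree(hc, h = 1 - cor_cut)
    # reattach straggler groups to their best-correlated large group
    sizes <- table(grp)
    small <- as.integer(names(sizes)[sizes < min_group_size])
    large <- as.integer(names(sizes)[sizes >= min_group_size])
    for (sg in small) {
      if (length(large) == 0L) break
      idx_s <- which(grp == sg)
      cross <- vapply(large, function(lg) {
        mean(cmat[idx_s, which(grp == lg), drop = FALSE])
      }, 0)
      if (max(cross) >= 0.5) grp[idx_s] <- large[which.max(cross)]
    }
    names(grp) <- significant
  }

  # relabel groups by size (largest first) for stable reporting
  sizes <- sort(table(grp), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  grp <- relabel[as.character(grp)]

  cell_info <- do.call(rbind, strsplit(colnames(prof), "|", fixed = TRUE))
  profiles <- do.call(rbind, lapply(sort(unique(grp)), function(gid) {
    mz <- colMeans(prof[grp == gid, , drop = FALSE])
    data.frame(group_id = gid, duration_ms = as.numeric(cell_info[, 1L]),
               tissue = cell_info[, 2L], mean_z = unname(mz),
               stringsAsFactors = FALSE)
  }))
  structure(list(membership = data.frame(gene_id = significant,
                                         group_id = unname(grp),
                                         stringsAsFactors = FALSE),
                 profiles = profiles,
                 n_groups = length(unique(grp)), cor_cut = cor_cut),
            class = "pattern_groups")
}

#' @export
print.pattern_groups <- function(x, ...) {
  cat(sprintf("pattern_groups: %d gene(s) in %d group(s) (cor cut %.2f)\n",
              nrow(x$membership), x$n_groups, x$cor_cut))
  invisible(x)
}

#' Select groups with EO-specific, duration-monotone expression
#'
#' A pattern group is selected when its mean profile satisfies both study
#' criteria: (i) EO expression exceeds SM expression at every duration, and
#' (ii) the EO values are strictly monotone across durations ordered by
#' `duration_ms`. The monotone sense labels the group (and its member genes)
#' `increasing` or `decreasing`.
#'
#' @param groups A `pattern_groups` object from [cluster_patterns()].
#' @return List with character vectors `increasing` and `decreasing` (gene
#'   ids) and `group_provenance` (`gene_id`, `group_id`, `direction` for the
#'   selected genes).
#' @export
select_duration_groups <- function(groups) {
  stopifnot(inherits(groups, "pattern_groups"))
  prov <- data.frame(gene_id = character(), group_id = integer(),
                     direction = character(), stringsAsFactors = FALSE)
  for (gid in sort(unique(groups$profiles$group_id))) {
    p <- groups$profiles[groups$profiles$group_id == gid, ]
    wide <- stats::reshape(p[, c("duration_ms", "tissue", "mean_z")],
                           idvar = "duration_ms", timevar = "tissue",
                           direction = "wide")
    wide <- wide[order(wide$duration_ms), ]
    eo <- wide$mean_z.EO
    sm <- wide$mean_z.SM
    if (any(is.na(eo)) || any(is.na(sm)) || any(eo <= sm)) next
    deltas <- diff(eo)
    dir <- if (all(deltas > 0)) "increasing"
           else if (all(deltas < 0)) "decreasing" else NA_character_
    if (is.na(dir)) next
    members <- groups$membership$gene_id[groups$membership$group_id == gid]
    prov <- rbind(prov, data.frame(gene_id = members, group_id = gid,
                                   direction = dir, stringsAsFactors = FALSE))
  }
  list(increasing = prov$gene_id[prov$direction == "increasing"],
       decreasing = prov$gene_id[prov$direction == "decreasing"],
       group_provenance = prov)
}
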