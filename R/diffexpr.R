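#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the size factor is the median
#' across genes of the ratio between that sample's count and the gene's
#' geometric mean over samples, computed over genes with no zero count. The
#' resulting factors are rescaled to geometric mean 1, so they are
#' interpretable as relative sequencing depths.
#'
#' @param counts Integer count matrix (genes x samples).
#' @return Named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- validate_count_matrix(counts)
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  logc <- log(counts)
  log_geo <- rowMeans(logc)
  usable <- is.finite(log_geo)          # genes expressed in every sample
  if (!any(usable))
    stop_estimation("no gene has nonzero counts in all samples; cannot estimate size factors")
  log_sf <- apply(logc[usable, , drop = FALSE], 2L,
                  function(x) stats::median(x - log_geo[usable]))
  sf <- exp(log_sf - mean(log_sf))      # geometric mean 1
  setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion estimates
#'
#' Method-of-moments estimation on size-factor-normalized counts within
#' replicate groups (cohort x tissue cells of the design), followed by
#' shrinkage half-way toward a fitted mean-dispersion trend
#' (`a0 + a1 / mean`, gamma-GLM fit as in the parametric DESeq trend). For a
#' normalized count `z = y / s`, the within-group variance satisfies
#' `Var(z) ~ mu * E(1/s) + alpha * mu^2`, which is solved for `alpha` per
#' group and pooled by residual degrees of freedom. Estimates are floored at
#' `1e-8` (a constant gene sits at the floor).
#'
#' @param counts Integer count matrix.
#' @param samples Sample sheet rows for the columns of `counts`; groups are
#'   `cohort x tissue`.
#' @param size_factors Optional size factors (estimated when `NULL`).
#' @param trend_shrink Weight of the trend in the final arithmetic average
#'   (0 = raw gene-wise estimates, default 0.5).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersions <- function(counts, samples, size_factors = NULL,
                                 trend_shrink = 0.5) {
  counts <- validate_count_matrix(counts)
  samples <- samples_for(samples, colnames(counts))
  group <- interaction(samples$cohort, samples$tissue, drop = TRUE)
  if (all(table(group) < 2L))
    stop_estimation("all groups are singletons; replication is required to estimate dispersion")
  sf <- size_factors %||% estimate_size_factors(counts)
  z <- sweep(counts, 2L, sf, "/")

  floor_disp <- 1e-8
  raw <- numeric(nrow(counts))
  mean_expr <- rowMeans(z)
  for (lev in levels(group)) {
    idx <- which(group == lev)
    if (length(idx) < 2L) next
    zi <- z[, idx, drop = FALSE]
    m <- rowMeans(zi)
    v <- apply(zi, 1L, stats::var)
    xi <- mean(1 / sf[idx])             # shot-noise term of Var(y/s)
    a <- (v - m * xi) / m^2
    a[!is.finite(a)] <- 0
    df <- length(idx) - 1L
    raw <- raw + df * a
  }
  total_df <- sum(pmax(table(group) - 1L, 0L))
  raw <- pmax(raw / total_df, floor_disp)

  trend <- fit_dispersion_trend(raw, mean_expr)
  disp <- pmax((1 - trend_shrink) * raw + trend_shrink * trend, floor_disp)
  setNames(disp, rownames(counts))
}

# Parametric dispersion trend alpha(mu) = a0 + a1/mu, iteratively reweighted
# gamma fit with outlier trimming; falls back to the median dispersion when
# too few usable genes or a degenerate fit.
fit_dispersion_trend <- function(disp, mean_expr) {
  usable <- disp > 1e-7 & mean_expr > 0
  pos <- disp[disp > 1e-7]
  fallback <- rep(if (length(pos)) stats::median(pos) else stats::median(disp),
                  length(disp))
  if (sum(usable) < 20L) return(fallback)
  d <- disp[usable]; m <- mean_expr[usable]
  coefs <- c(a0 = stats::median(d), a1 = 0)
  for (it in 1:3) {
    fit <- try(suppressWarnings(
      stats::glm(d ~ I(1 / m), family = stats::Gamma(link = "identity"),
                 start = pmax(coefs, 1e-6))), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) break
    coefs <- pmax(stats::coef(fit), 0)
    ratio <- d / pmax(coefs[1] + coefs[2] / m, 1e-8)
    keep <- ratio > 1e-4 & ratio < 15
    d <- d[keep]; m <- m[keep]
    if (length(d) < 20L) break
  }
  if (all(coefs == 0)) return(fallback)
  pmax(coefs[1] + coefs[2] / pmax(mean_expr, 1e-8), 1e-8)
}

# One NB GLM fit with fixed dispersion (theta = 1/alpha), via IRLS.
# Returns coefficients, their covariance, deviance and convergence flag.
nb_glm_fit <- function(y, X, dispersion, offset) {
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = list(maxit = 50L)))
  p <- fit$rank
  covu <- matrix(NA_real_, ncol(X), ncol(X))
  if (p > 0L) {
    piv <- fit$qr$pivot[seq_len(p)]
    covu[piv, piv] <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  }
  list(coef = fit$coefficients, vcov = covu, deviance = fit$deviance,
       converged = fit$converged && all(is.finite(fit$coefficients)))
}

#' Per-cohort EO-vs-SM Wald test
#'
#' For one cohort, fits each gene with a negative-binomial log-link GLM
#' (intercept + tissue indicator, SM as reference, log size factors as
#' offset) at the gene's estimated dispersion, and tests the tissue
#' coefficient against the standard-normal reference. P-values are
#' Benjamini-Hochberg adjusted within the cohort. Genes whose IRLS fit does
#' not converge are flagged (`converged = FALSE`) with missing p-values and
#' are never silently dropped.
#'
#' @param counts Integer count matrix covering (at least) the cohort samples.
#' @param samples Sample sheet.
#' @param cohort Cohort label to analyse; both tissues must be present with
#'   at least two replicates each.
#' @param size_factors,dispersions Optional precomputed values for the cohort
#'   columns; estimated within the cohort when `NULL`.
#' @return A `data.frame` with one row per gene: `gene_id`, `log2fc` (EO
#'   relative to SM), `se_log2fc`, `wald_stat`, `p_value`, `p_adj`,
#'   `mean_expr` (mean normalized count), `converged`.
#' @export
wald_test_tissue <- function(counts, samples, cohort,
                             size_factors = NULL, dispersions = NULL) {
  counts <- validate_count_matrix(counts)
  sub <- samples[samples$cohort == cohort, , drop = FALSE]
  if (nrow(sub) == 0L) stop_validation("cohort '%s' not present in sample sheet", cohort)
  missing_cols <- setdiff(sub$sample_id, colnames(counts))
  if (length(missing_cols) > 0L)
    stop_validation("count matrix lacks sample(s): %s",
                    paste(missing_cols, collapse = ", "))
  n_by_tissue <- table(factor(sub$tissue, levels = c("SM", "EO")))
  if (any(n_by_tissue < 2L))
    stop_validation("cohort '%s' needs both tissues with >= 2 replicates (got SM=%d, EO=%d)",
                    cohort, n_by_tissue["SM"], n_by_tissue["EO"])

  cm <- counts[, sub$sample_id, drop = FALSE]
  sf <- size_factors %||% estimate_size_factors(cm)
  disp <- dispersions %||% estimate_dispersions(cm, sub, size_factors = sf)
  tissue <- factor(sub$tissue, levels = c("SM", "EO"))
  X <- stats::model.matrix(~tissue)
  offset <- log(sf)
  norm_mean <- rowMeans(sweep(cm, 2L, sf, "/"))

  n_genes <- nrow(cm)
  log2fc <- se <- wald <- pval <- rep(NA_real_, n_genes)
  conv <- rep(FALSE, n_genes)
  for (g in seq_len(n_genes)) {
    y <- cm[g, ]
    if (all(y == 0)) next
    fit <- nb_glm_fit(y, X, disp[g], offset)
    b <- fit$coef[2L]; v <- fit$vcov[2L, 2L]
    if (!fit$converged || !is.finite(b) || !is.finite(v) || v <= 0) next
    conv[g] <- TRUE
    log2fc[g] <- b / log(2)
    se[g] <- sqrt(v) / log(2)
    wald[g] <- b / sqrt(v)
    pval[g] <- 2 * stats::pnorm(-abs(wald[g]))
  }
  data.frame(gene_id = rownames(cm), log2fc = log2fc, se_log2fc = se,
             wald_stat = wald, p_value = pval,
             p_adj = stats::p.adjust(pval, method = "BH"),
             mean_expr = norm_mean, converged = conv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially expressed genes
#'
#' Applies the DEG rule with strict inequalities: upregulated when
#' `log2fc > lfc_threshold` and significant; downregulated when
#' `log2fc < -lfc_threshold` and significant. Significance uses the
#' BH-adjusted p-value by default (`p_adj < alpha`); set
#' `use_adjusted = FALSE` for the raw-p reading. Non-converged genes are
#' excluded.
#'
#' @param results Output of [wald_test_tissue()] for one cohort.
#' @param lfc_threshold Absolute log2 fold-change threshold (exclusive).
#' @param alpha Significance threshold (exclusive).
#' @param use_adjusted Use `p_adj` (default) or raw `p_value`.
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(results, lfc_threshold = 1, alpha = 0.05,
                      use_adjusted = TRUE) {
  p <- if (use_adjusted) results$p_adj else results$p_value
  ok <- results$converged & !is.na(p) & !is.na(results$log2fc)
  list(up = results$gene_id[ok & results$log2fc > lfc_threshold & p < alpha],
       down = results$gene_id[ok & results$log2fc < -lfc_threshold & p < alpha])
}

#' Shared DEGs across cohorts
#'
#' Intersects the per-cohort up- and downregulated DEG sets separately (the
#' Venn-intersection of the study design): a shared gene is called in the
#' same direction in every cohort.
#'
#' @param per_cohort Named list (one entry per cohort) of [call_degs()]
#'   results.
#' @return List with `up_shared`, `down_shared`, `per_cohort_up`,
#'   `per_cohort_down`.
#' @export
shared_degs <- function(per_cohort) {
  if (length(per_cohort) < 2L)
    stop_validation("shared_degs needs at least 2 cohorts")
  ups <- lapply(per_cohort, `[[`, "up")
  downs <- lapply(per_cohort, `[[`, "down")
  list(up_shared = sort(Reduce(intersect, ups)),
       down_shared = sort(Reduce(intersect, downs)),
       per_cohort_up = ups, per_cohort_down = downs)
}
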