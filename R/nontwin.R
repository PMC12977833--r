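# Variance-QTL tests for unrelated individuals: DRM and SVLM.

check_singleton_design <- function(phenotype, genotype, min_per_group = 2L) {
  stopifnot(length(phenotype) == length(genotype))
  grp <- round(genotype)
  counts <- table(grp)
  if (length(counts) < 2) rlang::abort("genotype is constant: degenerate design")
  if (any(counts < min_per_group)) {
    rlang::abort(sprintf("every genotype group needs >= %d observations", min_per_group))
  }
  factor(grp)
}

#' Deviation regression model (DRM) variance test
#'
#' Each sample's distance to the median of its genotype group,
#' `d_i = |y_i - median(y, group i)|`, is regressed on the additive dosage;
#' the slope t-test detects genotype effects on phenotype spread. Groups are
#' formed from dosages rounded to hard calls; the raw dosage is the
#' regressor. A constant phenotype yields slope 0 and `p = 1`.
#'
#' @param phenotype Covariate-adjusted phenotype vector.
#' @param genotype Dosage vector.
#' @return One-row tibble: `method = "DRM"`, `slope`, `se`, `statistic`,
#'   `p`, `n`, `n_g0`, `n_g1`, `n_g2`.
#' @export
drm_test <- function(phenotype, genotype) {
  grp <- check_singleton_design(phenotype, genotype)
  med <- tapply(phenotype, grp, stats::median)
  d <- abs(phenotype - med[as.character(grp)])
  fit <- ols_slope_test(d, cbind(intercept = 1, genotype = genotype), 2L)
  counts <- tabulate(round(genotype) + 1L, nbins = 3L)
  tibble::tibble(
    method = "DRM", slope = fit$estimate, se = fit$se,
    statistic = fit$statistic, p = fit$p, n = length(phenotype),
    n_g0 = counts[1], n_g1 = counts[2], n_g2 = counts[3]
  )
}

#' Squared-residual linear model (SVLM) variance test
#'
#' Stage 1 regresses the phenotype on dosage (removing the mean genotype
#' effect); stage 2 regresses the squared stage-1 residuals on dosage. The
#' stage-2 slope t-test detects variance heterogeneity across genotypes and
#' is insensitive to pure mean-level QTLs by construction.
#'
#' @inheritParams drm_test
#' @return One-row tibble as [drm_test()] with `method = "SVLM"`.
#' @export
svlm_test <- function(phenotype, genotype) {
  check_singleton_design(phenotype, genotype)
  r <- ols_residuals(phenotype, cbind(1, genotype))
  fit <- ols_slope_test(r^2, cbind(intercept = 1, genotype = genotype), 2L)
  counts <- tabulate(round(genotype) + 1L, nbins = 3L)
  tibble::tibble(
    method = "SVLM", slope = fit$estimate, se = fit$se,
    statistic = fit$statistic, p = fit$p, n = length(phenotype),
    n_g0 = counts[1], n_g1 = counts[2], n_g2 = counts[3]
  )
}

#' Joint DRM + SVLM FDR replication
#'
#' An association replicates only when it is FDR-significant (BH, within
#' method) under both the DRM and the SVLM test.
#'
#' @param drm_results,svlm_results Tibbles with key columns (e.g. `cpg`,
#'   `snp`) and `p`.
#' @param keys Key column names (default `c("cpg", "snp")`).
#' @param fdr FDR level (default 0.05).
#' @return Tibble of jointly significant associations with per-method
#'   q-values.
#' @export
joint_fdr_replication <- function(drm_results, svlm_results,
                                  keys = c("cpg", "snp"), fdr = 0.05) {
  if (nrow(drm_results) == 0 || nrow(svlm_results) == 0) {
    return(tibble::tibble())
  }
  a <- dplyr::mutate(drm_results, q_drm = stats::p.adjust(.data$p, "BH"))
  b <- dplyr::mutate(svlm_results, q_svlm = stats::p.adjust(.data$p, "BH"))
  dplyr::inner_join(
    dplyr::filter(a, .data$q_drm < fdr)[, c(keys, "q_drm")],
    dplyr::filter(b, .data$q_svlm < fdr)[, c(keys, "q_svlm")],
    by = keys
  )
}
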