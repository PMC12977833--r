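# Cis QTL mapping with permutation-calibrated beta-approximated p-values.

# Standardize rows of a matrix to zero mean / unit SD. Rows with zero
# variance are flagged NA.
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  cm <- m - mu
  s <- sqrt(rowSums(cm^2) / (ncol(m) - 1))
  cm / ifelse(s > 0, s, NA_real_)
}

# Two-sided p-value of a Pearson correlation with n observations.
cor_pval <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  2 * stats::pt(t, n - 2, lower.tail = FALSE)
}

# Maximum-likelihood beta fit (method-of-moments init). Returns
# list(shape1, shape2, ok).
fit_beta_mle <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(list(shape1 = NA, shape2 = NA, ok = FALSE))
  common <- m * (1 - m) / v - 1
  if (common <= 0) common <- 1
  init <- log(c(max(m * common, 1e-3), max((1 - m) * common, 1e-3)))
  nll <- function(lp) -sum(stats::dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(
    stats::optim(init, nll, method = "BFGS"),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value)) {
    return(list(shape1 = NA, shape2 = NA, ok = FALSE))
  }
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]), ok = TRUE)
}

# In-window SNP ids for one CpG (inclusive window endpoints).
cis_window_snps <- function(snp_pos, cpg_chrom, cpg_position, window_bp) {
  snp_pos$id[snp_pos$chrom == cpg_chrom &
    abs(snp_pos$pos - cpg_position) <= window_bp]
}

#' Cis QTL scan with permutation beta-approximation
#'
#' For each CpG, tests all SNPs within `window_bp` of the CpG position
#' (inclusive, same chromosome) against the supplied covariate-adjusted
#' per-pair residuals, keeping the most significant nominal p-value
#' (`p_true`). The residual vector is then permuted across pairs `n_perm`
#' times; the minimum in-window p-value of each permutation is recorded and
#' the set of minima is fitted to a beta distribution by maximum likelihood.
#' The empirical p-value `p_beta` is the beta CDF at `p_true`. Storey
#' q-values are computed over all tested CpGs; CpGs with `q < q_threshold`
#' carry a significant cis QTL, and each receives a per-CpG nominal
#' significance threshold `nominal_threshold`, the beta quantile at the
#' global `p_beta` cutoff implied by the q-value crossing (linear
#' interpolation between the last significant and first non-significant
#' sorted `p_beta`).
#'
#' If the beta fit fails for a CpG, `p_beta` falls back to the empirical
#' permutation rank p-value `(1 + #{min_p <= p_true}) / (n_perm + 1)` and
#' the CpG is flagged `beta_ok = FALSE`.
#'
#' @param residuals Numeric matrix of covariate-adjusted residuals, CpGs in
#'   rows, pairs in columns (e.g. stacked [residualize_difference()]
#'   output), or a single named vector for one CpG.
#' @param genotypes Dosage matrix, SNPs x pairs, columns aligned with
#'   `residuals`.
#' @param snp_pos,cpg_pos Position tibbles (`id`, `chrom`, `pos`).
#' @param window_bp Cis window half-width in bp (default 1e6).
#' @param n_perm Number of permutations per CpG (default 10000).
#' @param q_threshold Global q-value cutoff (default 0.05).
#' @param qvalue_method `"storey"` or `"bh"`.
#' @param seed Master seed; per-CpG permutation seeds are derived from it.
#' @return Tibble of class `cis_scan`: one row per CpG with `cpg`,
#'   `lead_snp`, `n_snps`, `slope`, `p_true`, `shape1`, `shape2`, `p_beta`,
#'   `beta_ok`, `q`, `significant`, `nominal_threshold`. CpGs without any
#'   in-window SNP are returned with `n_snps = 0` and NA results.
#' @export
cis_scan <- function(residuals, genotypes, snp_pos, cpg_pos,
                     window_bp = 1e6, n_perm = 10000, q_threshold = 0.05,
                     qvalue_method = "storey", seed = 1L) {
  if (is.null(dim(residuals))) {
    residuals <- matrix(residuals,
      nrow = 1,
      dimnames = list(cpg_pos$id[1], names(residuals))
    )
  }
  stopifnot(ncol(residuals) == ncol(genotypes))
  snp_pos <- tibble::as_tibble(snp_pos)
  cpg_pos <- tibble::as_tibble(cpg_pos)
  cpgs <- rownames(residuals)
  n <- ncol(residuals)
  G_std <- standardize_rows(genotypes)
  cpg_seeds <- derive_seeds(seed, length(cpgs))

  rows <- purrr::map(seq_along(cpgs), function(i) {
    cpg <- cpgs[i]
    info <- cpg_pos[cpg_pos$id == cpg, ]
    if (nrow(info) != 1) rlang::abort(sprintf("no position for CpG %s", cpg))
    snps <- cis_window_snps(snp_pos, info$chrom, info$pos, window_bp)
    snps <- snps[!is.na(G_std[snps, 1])] # drop zero-variance dosages
    if (length(snps) == 0) {
      return(tibble::tibble(
        cpg = cpg, lead_snp = NA_character_, n_snps = 0L,
        slope = NA_real_, p_true = NA_real_, shape1 = NA_real_,
        shape2 = NA_real_, p_beta = NA_real_, beta_ok = NA
      ))
    }
    Gw <- G_std[snps, , drop = FALSE]
    y <- as.numeric(residuals[cpg, ])
    y_std <- (y - mean(y)) / stats::sd(y)
    r_obs <- as.numeric(Gw %*% y_std) / (n - 1)
    p_obs <- cor_pval(r_obs, n)
    best <- which.max(abs(r_obs))
    # slope on the raw dosage scale for the lead SNP
    g_raw <- genotypes[snps[best], ]
    slope <- stats::cov(y, g_raw) / stats::var(g_raw)

    set.seed(cpg_seeds[i])
    P <- matrix(0, nrow = n_perm, ncol = n)
    for (b in seq_len(n_perm)) P[b, ] <- y_std[sample.int(n)]
    max_abs_r <- apply(abs(P %*% t(Gw)) / (n - 1), 1, max)
    perm_min_p <- cor_pval(max_abs_r, n)

    bf <- fit_beta_mle(perm_min_p)
    p_true <- p_obs[best]
    p_beta <- if (bf$ok) {
      stats::pbeta(p_true, bf$shape1, bf$shape2)
    } else {
      (1 + sum(perm_min_p <= p_true)) / (n_perm + 1)
    }
    tibble::tibble(
      cpg = cpg, lead_snp = snps[best], n_snps = length(snps),
      slope = slope, p_true = p_true, shape1 = bf$shape1,
      shape2 = bf$shape2, p_beta = p_beta, beta_ok = bf$ok
    )
  })
  out <- dplyr::bind_rows(rows)

  tested <- !is.na(out$p_beta)
  out$q <- NA_real_
  if (any(tested)) {
    out$q[tested] <- as.numeric(storey_qvalue(out$p_beta[tested], method = qvalue_method))
  }
  out$significant <- !is.na(out$q) & out$q < q_threshold
  pt_beta <- pbeta_threshold(out$p_beta[tested], out$q[tested], q_threshold)
  out$nominal_threshold <- ifelse(
    tested & out$beta_ok %in% TRUE & !is.na(pt_beta),
    stats::qbeta(pt_beta, out$shape1, out$shape2), NA_real_
  )
  class(out) <- c("cis_scan", class(out))
  attr(out, "pt_beta") <- pt_beta
  attr(out, "window_bp") <- window_bp
  attr(out, "n_perm") <- n_perm
  out
}

# Global p_beta cutoff implied by the q-value crossing: linear interpolation
# (midpoint) between the largest significant and smallest non-significant
# sorted p_beta. Returns NA if nothing is significant; the largest p_beta
# if everything is.
pbeta_threshold <- function(p_beta, q, q_threshold) {
  ok <- !is.na(p_beta) & !is.na(q)
  p_beta <- p_beta[ok]
  q <- q[ok]
  if (length(p_beta) == 0 || !any(q < q_threshold)) return(NA_real_)
  sig_max <- max(p_beta[q < q_threshold])
  nonsig <- p_beta[q >= q_threshold & p_beta > sig_max]
  if (length(nonsig) == 0) return(sig_max)
  (sig_max + min(nonsig)) / 2
}

#' Conditional cis scan: one forward step past the lead SNP
#'
#' For each CpG with a significant cis QTL, regresses the lead SNP's dosage
#' out of the residual vector and rescans the cis window with the same
#' permutation scheme. Secondary signals are reported when their
#' beta-approximated p-value falls below the global `p_beta` cutoff of the
#' primary scan.
#'
#' @param cis_results A `cis_scan` result.
#' @param residuals,genotypes,snp_pos,cpg_pos As in [cis_scan()].
#' @param seed Seed for the conditional permutations.
#' @return Tibble of secondary signals (possibly empty) with the same
#'   columns as [cis_scan()] plus `conditioned_on`.
#' @export
conditional_cis_scan <- function(cis_results, residuals, genotypes,
                                 snp_pos, cpg_pos, seed = 2L) {
  stopifnot(inherits(cis_results, "cis_scan"))
  pt_beta <- attr(cis_results, "pt_beta")
  hits <- dplyr::filter(cis_results, .data$significant)
  if (nrow(hits) == 0 || is.na(pt_beta)) {
    return(tibble::tibble())
  }
  if (is.null(dim(residuals))) {
    residuals <- matrix(residuals, nrow = 1, dimnames = list(hits$cpg[1], names(residuals)))
  }
  out <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    cpg <- hits$cpg[i]
    lead <- hits$lead_snp[i]
    g_lead <- genotypes[lead, ]
    if (stats::var(g_lead) == 0) rlang::abort("lead SNP dosage is constant")
    y <- as.numeric(residuals[cpg, ])
    y_adj <- ols_residuals(y, cbind(1, g_lead))
    res2 <- cis_scan(
      stats::setNames(y_adj, colnames(residuals)),
      genotypes,
      snp_pos, cpg_pos[cpg_pos$id == cpg, ],
      window_bp = attr(cis_results, "window_bp"),
      n_perm = attr(cis_results, "n_perm"),
      seed = seed + i
    )
    dplyr::mutate(res2[, setdiff(names(res2), c("q", "significant", "nominal_threshold"))],
      conditioned_on = lead,
      secondary_significant = !is.na(.data$p_beta) & .data$p_beta < pt_beta
    )
  })
  dplyr::filter(out, .data$secondary_significant)
}
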