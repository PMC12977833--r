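# Shared fixtures and independent oracles, all built in code.

# Tiny deterministic twin cohort: n_pairs pairs, one SNP block + distant CpGs
# are not needed here; methylation rows supplied by the caller or random.
make_tiny_cohort <- function(n_pairs = 30, n_cpgs = 2, seed = 99,
                             scale = "beta") {
  set.seed(seed)
  covariates <- simulate_covariates(n_pairs)
  covariates$batch <- sample(c("b1", "b2"), nrow(covariates), replace = TRUE)
  genotype <- matrix(
    simulate_genotype(n_pairs, maf = 0.4, min_group = 1L),
    nrow = 1, dimnames = list("snp1", unique(covariates$pair_id))
  )
  meth <- matrix(stats::runif(n_cpgs * nrow(covariates)),
    nrow = n_cpgs,
    dimnames = list(
      sprintf("cpg%02d", seq_len(n_cpgs)),
      covariates$individual_id
    )
  )
  twin_cohort(
    covariates = covariates, genotype = genotype, methylation = meth,
    snp_pos = tibble::tibble(id = "snp1", chrom = "chr1", pos = 1000L),
    cpg_pos = tibble::tibble(
      id = rownames(meth), chrom = "chr1",
      pos = seq(2000L, by = 1000L, length.out = n_cpgs)
    ),
    scale = scale
  )
}

# Closed-form OLS via the normal equations — independent of the package's
# QR-based path.
normal_equations_residuals <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

normal_equations_slope_test <- function(y, X, coef = 2) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  se <- sqrt(drop(crossprod(res)) / df * XtXi[coef, coef])
  stat <- beta[coef] / se
  list(
    estimate = beta[coef], se = se, statistic = stat,
    p = 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  )
}

# Independent greedy-clumping oracle: straight transliteration of the rule,
# using plain loops and explicit cor() calls.
clump_oracle <- function(snps, p, genotypes, positions, window_bp, r2) {
  info <- as.data.frame(positions[match(snps, positions$id), ])
  remaining <- seq_along(snps)
  assign <- rep(NA_character_, length(snps))
  while (length(remaining) > 0) {
    ord <- remaining[order(p[remaining], info$chrom[remaining],
      info$pos[remaining], snps[remaining])]
    i <- ord[1]
    assign[i] <- snps[i]
    remaining <- setdiff(remaining, i)
    for (j in remaining) {
      if (info$chrom[j] == info$chrom[i] &&
        abs(info$pos[j] - info$pos[i]) <= window_bp) {
        r <- stats::cor(genotypes[snps[i], ], genotypes[snps[j], ])
        if (!is.na(r) && r^2 >= r2) assign[j] <- snps[i]
      }
    }
    remaining <- remaining[is.na(assign[remaining])]
  }
  assign
}

# Exhaustive two-tailed Fisher p by hypergeometric enumeration.
fisher_oracle_p <- function(a, b, c_, d) {
  m <- a + b # query size
  k <- a + c_ # annotation size
  n_tot <- a + b + c_ + d
  lo <- max(0, k + m - n_tot)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_tot - m, k)
  obs <- stats::dhyper(a, m, n_tot - m, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Empirical permutation p-value for the best cis association of one CpG:
# the high-resolution oracle the beta approximation is checked against.
empirical_cis_p <- function(y, G, n_perm, seed) {
  set.seed(seed)
  n <- length(y)
  y_std <- (y - mean(y)) / stats::sd(y)
  G_std <- t(apply(G, 1, function(g) (g - mean(g)) / stats::sd(g)))
  r_obs <- max(abs(G_std %*% y_std) / (n - 1))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    r_b <- max(abs(G_std %*% y_std[sample.int(n)]) / (n - 1))
    if (r_b >= r_obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}
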