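test_that("SNP QC applies the HWE, MAF and group-size rules", {
  # full disequilibrium: (100, 0, 100) -> chi-square ~ n, p << 1e-6
  g_bad <- matrix(rep(c(0, 2), each = 100), nrow = 1,
    dimnames = list("bad", NULL))
  out <- filter_snps(g_bad)
  expect_false(out$keep)
  expect_equal(out$reason, "hwe")
  expect_lt(out$hwe_p, 1e-6)

  # balanced HWE SNP is kept
  g_ok <- matrix(c(rep(0, 90), rep(1, 170), rep(2, 90)), nrow = 1,
    dimnames = list("ok", NULL))
  expect_true(filter_snps(g_ok)$keep)

  # (340, 7, 3) is dropped: 3 minor homozygotes against 0.12 expected is
  # also a gross HWE violation, so the first-failed-rule code is "hwe"
  g_small <- matrix(c(rep(0, 340), rep(1, 7), rep(2, 3)), nrow = 1,
    dimnames = list("small", NULL))
  out <- filter_snps(g_small)
  expect_false(out$keep)
  # HWE-consistent counts with a minor-homozygote group of 4 (< 5):
  # only the group rule fires
  g_grp <- matrix(c(rep(0, 280), rep(1, 66), rep(2, 4)), nrow = 1,
    dimnames = list("grp", NULL))
  out2 <- filter_snps(g_grp)
  expect_false(out2$keep)
  expect_equal(out2$reason, "group_size")
  expect_gt(out2$hwe_p, 1e-6)

  expect_error(filter_snps(matrix(c(0, 0.5, 1), nrow = 1)), "hard calls")
})

test_that("probe filter drops any missingness", {
  m <- matrix(stats::runif(30), nrow = 3,
    dimnames = list(c("a", "b", "c"), NULL))
  m[2, 5] <- NA
  m[3, ] <- NA
  out <- filter_probes(m)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE))
  expect_equal(out$n_missing, c(0L, 1L, 10L))
})

test_that("storey q-values are monotone, bounded, and BH-consistent", {
  set.seed(31)
  p <- c(stats::runif(400), stats::rbeta(100, 0.2, 6))
  q <- storey_qvalue(p)
  pi0 <- attr(q, "pi0")
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(as.numeric(q)[order(p)]) >= -1e-12))
  expect_lte(pi0, 1)
  # pi0-scaled BH never above plain BH
  expect_true(all(q <= stats::p.adjust(p, "BH") + 1e-12))
  # BH mode equals p.adjust
  expect_equal(as.numeric(storey_qvalue(p, method = "bh")),
    pmin(stats::p.adjust(p, "BH"), 1))
})

test_that("beta MLE recovers known shape parameters", {
  set.seed(32)
  x <- stats::rbeta(5000, 0.9, 40)
  f <- twinvqtl:::fit_beta_mle(x)
  expect_true(f$ok)
  expect_lt(abs(f$shape1 - 0.9) / 0.9, 0.1)
  expect_lt(abs(f$shape2 - 40) / 40, 0.1)
})

test_that("cis scan agrees with the empirical permutation oracle and calls truth", {
  coh <- simulate_cohort_genome(
    n_pairs = 250, n_snps = 40, n_cpgs = 10, ld_block_size = 4,
    classes = c("null", "vmeqtl"), a_GxE = 0.25, seed = 33
  )
  res_abs <- do.call(rbind, lapply(
    rownames(coh$methylation),
    function(cpg) residualize_difference(coh, cpg)
  ))
  rownames(res_abs) <- rownames(coh$methylation)
  scan <- cis_scan(res_abs, coh$genotype, coh$snp_pos, coh$cpg_pos,
    n_perm = 1500, seed = 34
  )
  expect_true(all(scan$p_beta >= 0 & scan$p_beta <= 1, na.rm = TRUE))
  # truth recovery: vmeqtl CpGs significant, lead in the causal block
  tr <- coh$truth
  vme <- tr$cpg[tr$class == "vmeqtl"]
  expect_true(all(scan$significant[scan$cpg %in% vme]))
  # q < 0.05 is an FDR, not a hard gate: allow at most one null false call
  expect_lte(sum(scan$significant[!scan$cpg %in% vme]), 1)

  # oracle: beta-approximated p within 0.05 of a high-resolution empirical p
  for (cpg in scan$cpg[c(1, 2)]) {
    info <- coh$cpg_pos[coh$cpg_pos$id == cpg, ]
    snps <- twinvqtl:::cis_window_snps(coh$snp_pos, info$chrom, info$pos, 1e6)
    emp <- empirical_cis_p(
      as.numeric(res_abs[cpg, ]),
      coh$genotype[snps, , drop = FALSE],
      n_perm = 2000, seed = 35
    )
    expect_lt(abs(scan$p_beta[scan$cpg == cpg] - emp), 0.05)
  }
})

test_that("cis scan handles CpGs without in-window SNPs and null calibration", {
  set.seed(36)
  n <- 120
  g <- matrix(sample(0:2, n * 5, TRUE, prob = c(0.36, 0.48, 0.16)),
    nrow = 5, dimnames = list(paste0("s", 1:5), paste0("p", 1:n)))
  snp_pos <- tibble::tibble(id = paste0("s", 1:5), chrom = "chr1",
    pos = seq(1e6, 5e6, length.out = 5))
  cpg_pos <- tibble::tibble(id = c("far", "near"), chrom = c("chr9", "chr1"),
    pos = c(1e6, 2e6))
  res <- matrix(stats::rnorm(2 * n), nrow = 2,
    dimnames = list(c("far", "near"), paste0("p", 1:n)))
  scan <- cis_scan(res, g, snp_pos, cpg_pos, n_perm = 300, seed = 37)
  expect_equal(scan$n_snps[scan$cpg == "far"], 0L)
  expect_true(is.na(scan$p_beta[scan$cpg == "far"]))
  expect_false(scan$significant[scan$cpg == "near"])

  # null p_beta is approximately uniform over replicates
  pb <- replicate(60, {
    y <- stats::rnorm(n)
    s <- cis_scan(stats::setNames(y, paste0("p", 1:n)), g, snp_pos,
      cpg_pos[2, ], n_perm = 250, seed = sample.int(1e6, 1))
    s$p_beta
  })
  ks <- stats::ks.test(pb, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("conditional cis scan finds a second unlinked signal and stops at one", {
  # two unlinked causal SNPs in the same window, both driving the variance
  # of one CpG; background null
  # CpGs give the scan a meaningful q-value crossing
  set.seed(38)
  n <- 350
  cov <- simulate_covariates(n)
  g1 <- simulate_genotype(n, 0.4)
  g2 <- simulate_genotype(n, 0.4)
  cfg <- sim_config(n_pairs = n, a_GxE = 0.3)
  y1 <- simulate_methylation(cfg, g1, cov)
  y2 <- simulate_methylation(cfg, g2, cov)
  # the two interaction terms share the smoking exposure, which dilutes the
  # per-SNP signal; 0.3 + 0.3 keeps both individually detectable
  y <- 0.3 * y1$gxe_term + 0.3 * y2$gxe_term +
    0.2 * y1$e_term + 0.2 * y1$noise_term
  pt <- twinvqtl:::pair_table(cov)
  t1 <- y[y1$twin == 1]; t2 <- y[y1$twin == 2]
  res <- twinvqtl:::residualize_pair_vectors(abs(t1 - t2), (t1 + t2) / 2, pt)
  n_null <- 6
  rv <- rbind(
    matrix(res$res_abs, nrow = 1),
    t(replicate(n_null, twinvqtl:::residualize_pair_vectors(
      abs(stats::rnorm(n, 0, 0.05)), stats::rnorm(n), pt)$res_abs))
  )
  dimnames(rv) <- list(c("cpgX", paste0("null", 1:n_null)), pt$pair_id)
  geno <- rbind(snpA = g1, snpB = g2)
  colnames(geno) <- pt$pair_id
  snp_pos <- tibble::tibble(id = c("snpA", "snpB"), chrom = "chr1",
    pos = c(1e6, 1.5e6))
  cpg_pos <- tibble::tibble(
    id = rownames(rv), chrom = "chr1",
    pos = c(1.2e6, seq(1.1e6, by = 1e5, length.out = n_null))
  )
  scan <- cis_scan(rv, geno, snp_pos, cpg_pos, n_perm = 1000, seed = 39)
  expect_true(scan$significant[scan$cpg == "cpgX"])
  sec <- conditional_cis_scan(scan, rv, geno, snp_pos, cpg_pos, seed = 40)
  expect_equal(nrow(sec), 1)
  expect_setequal(
    c(scan$lead_snp[scan$cpg == "cpgX"], sec$lead_snp),
    c("snpA", "snpB")
  )

  # constant lead dosage is refused
  geno_bad <- geno
  geno_bad[scan$lead_snp[scan$cpg == "cpgX"], ] <- 1
  expect_error(
    conditional_cis_scan(scan, rv, geno_bad, snp_pos, cpg_pos),
    "constant"
  )
})

test_that("trans scan arithmetic, null behaviour, and strong-signal detection", {
  coh <- simulate_cohort_genome(
    n_pairs = 250, n_snps = 30, n_cpgs = 12, ld_block_size = 3,
    classes = "null", seed = 41
  )
  res_abs <- do.call(rbind, lapply(
    rownames(coh$methylation),
    function(cpg) residualize_difference(coh, cpg)
  ))
  rownames(res_abs) <- rownames(coh$methylation)

  # pure null: no threshold reaches FDR 0.05
  null_scan <- trans_scan(res_abs, coh$genotype, coh$snp_pos, coh$cpg_pos,
    n_perm = 20, seed = 42
  )
  expect_true(is.na(null_scan$threshold) || nrow(null_scan$pairs) <= 2)

  # implant one strong trans effect: CpG on chr1, causal SNP on chr2
  tr_cpg <- coh$cpg_pos$id[coh$cpg_pos$chrom == "chr1"][1]
  tr_snp <- coh$snp_pos$id[coh$snp_pos$chrom == "chr2"][1]
  g <- coh$genotype[tr_snp, ]
  res_sig <- res_abs
  res_sig[tr_cpg, ] <- res_sig[tr_cpg, ] + 0.08 * g[colnames(res_sig)]
  scan <- trans_scan(res_sig, coh$genotype, coh$snp_pos, coh$cpg_pos,
    n_perm = 20, seed = 43
  )
  expect_false(is.na(scan$threshold))
  expect_true(any(scan$pairs$cpg == tr_cpg & scan$pairs$snp == tr_snp))
  # the reported FDR reproduces the counting formula
  expect_equal(
    scan$fdr_at_threshold,
    (scan$n_perm_below / scan$n_real_below) / 20
  )
  expect_lte(scan$fdr_at_threshold, 0.05)
})

test_that("greedy LD clumping equals the brute-force oracle on random instances", {
  set.seed(44)
  for (iter in 1:40) {
    n_snp <- 12
    n <- 150
    base <- sample(0:2, n, TRUE, prob = c(0.3, 0.5, 0.2))
    G <- matrix(NA_integer_, n_snp, n,
      dimnames = list(paste0("s", 1:n_snp), NULL))
    for (i in seq_len(n_snp)) {
      flip <- stats::runif(n) < stats::runif(1, 0, 0.8)
      gi <- base
      gi[flip] <- sample(0:2, sum(flip), TRUE, prob = c(0.3, 0.5, 0.2))
      G[i, ] <- gi
    }
    pos <- tibble::tibble(
      id = rownames(G),
      chrom = sample(c("chr1", "chr2"), n_snp, TRUE),
      pos = sample.int(2e6, n_snp)
    )
    p <- stats::runif(n_snp)
    got <- ld_clump(rownames(G), p, G, pos, window_bp = 5e5, r2_threshold = 0.2)
    want <- clump_oracle(rownames(G), p, G, pos, 5e5, 0.2)
    got_assign <- got$clumps$index_snp[match(rownames(G), got$clumps$member_snp)]
    expect_equal(got_assign, unname(want))
    # partition property: every SNP in exactly one clump
    expect_setequal(got$clumps$member_snp, rownames(G))
    expect_equal(nrow(got$clumps), n_snp)
  }
})

test_that("clumping degenerate cases behave as specified", {
  G <- rbind(
    a = c(0, 1, 2, 0, 1, 2, 1, 1, 0, 2),
    b = c(0, 1, 2, 0, 1, 2, 1, 1, 0, 2), # identical to a
    c = c(0, 2, 1, 2, 0, 1, 2, 1, 0, 1)
  )
  pos <- tibble::tibble(id = c("a", "b", "c"), chrom = "chr1",
    pos = c(100e3, 110e3, 120e3))
  cl <- ld_clump(c("a", "b", "c"), c(0.5, 0.01, 0.9), G, pos)
  # identical SNPs share a clump; smaller p is index
  expect_equal(cl$clumps$index_snp[cl$clumps$member_snp == "a"], "b")
  expect_equal(cl$clumps$index_snp[cl$clumps$member_snp == "b"], "b")
  # mutually uncorrelated SNP is its own index
  expect_equal(cl$clumps$index_snp[cl$clumps$member_snp == "c"], "c")
})

test_that("spurious-vmeQTL removal follows the dominance rule", {
  G <- rbind(
    lead_me = c(0, 1, 2, 0, 1, 2, 1, 1, 0, 2, 0, 1),
    tag = c(0, 1, 2, 0, 1, 2, 1, 1, 0, 2, 1, 0), # high r2 with lead_me
    free = c(2, 0, 1, 1, 2, 0, 0, 1, 2, 1, 2, 0)
  )
  pos <- tibble::tibble(id = rownames(G), chrom = "chr1",
    pos = c(1e6, 1.1e6, 1.2e6))
  vme <- tibble::tibble(cpg = c("c1", "c2"), snp = c("tag", "free"),
    p = c(1e-4, 1e-6))
  me <- tibble::tibble(cpg = "c1", snp = "lead_me", p = 1e-10)
  out <- remove_spurious_vmeqtls(vme, me, G, pos)
  expect_equal(out$kept$snp, "free")
  expect_equal(out$audit$discarded_snp, "tag")
  expect_equal(out$audit$dominating_meqtl, "lead_me")

  # vmeQTL stronger than the mean signal in the clump: retained
  me_weak <- tibble::tibble(cpg = "c1", snp = "lead_me", p = 1e-2)
  out2 <- remove_spurious_vmeqtls(vme, me_weak, G, pos)
  expect_setequal(out2$kept$snp, c("tag", "free"))
})

test_that("region exclusion uses the half-open convention", {
  cpgs <- tibble::tibble(id = c("x", "y", "z"), chrom = "chr1",
    pos = c(100L, 150L, 200L))
  regions <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  kept <- exclude_regions(cpgs, regions)
  # pos = start inside, pos = end outside
  expect_setequal(kept$id, "z")
  expect_equal(exclude_regions(cpgs, regions[0, ]), cpgs)
})

test_that("correlation filter and Bonferroni replication conventions", {
  x <- stats::rnorm(56)
  expect_true(correlation_filter(x, x)$keep)
  expect_false(correlation_filter(x, -x)$keep)
  expect_error(correlation_filter(1:2, 2:1), "fewer than 3")
  # independent noise is usually dropped at rho >= 0.2 with n = 56
  set.seed(45)
  drops <- mean(replicate(200, !correlation_filter(stats::rnorm(56), stats::rnorm(56))$keep))
  expect_gt(drops, 0.5)

  rep_tbl <- tibble::tibble(p = c(0.05 / 3, 0.01, 1))
  out <- bonferroni_replicate(rep_tbl)
  # boundary p = alpha/m is NOT significant (strict <)
  expect_equal(out$replicated, c(FALSE, TRUE, FALSE))
  one <- bonferroni_replicate(tibble::tibble(p = 0.04))
  expect_true(one$replicated)
})
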