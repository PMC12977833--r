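test_that("covariates respect the stated distributions and pair sharing", {
  cov <- simulate_covariates(350, seed = 1)
  expect_equal(nrow(cov), 700)
  expect_true(all(cov$age >= 20 & cov$age <= 70))
  expect_true(all(cov$sex %in% 0:1))
  expect_true(all(cov$smoking %in% 0:1))
  # age and sex shared within pair
  by_pair <- split(cov, cov$pair_id)
  expect_true(all(vapply(by_pair, function(d) length(unique(d$age)) == 1, logical(1))))
  expect_true(all(vapply(by_pair, function(d) length(unique(d$sex)) == 1, logical(1))))

  # smoking prevalence within 3 binomial SEs of 0.1 at large n
  big <- simulate_covariates(10000, seed = 2)
  se <- sqrt(0.1 * 0.9 / 20000)
  expect_lt(abs(mean(big$smoking) - 0.1), 3 * se)
  # BMI mixture: population SD between the two regime SDs
  expect_gt(stats::sd(big$bmi), 1)
  expect_lt(stats::sd(big$bmi), 3)
  expect_error(simulate_covariates(0), "n_pairs")
})

test_that("genotype simulation honours HWE and the group-size rule", {
  g <- simulate_genotype(350, maf = 0.5, seed = 3)
  expect_true(all(table(g) >= 5))
  big <- simulate_genotype(1e5, maf = 0.5, seed = 4)
  se <- sqrt(0.5 / 1e5) # var of dosage at maf 0.5 is 0.5
  expect_lt(abs(mean(big) - 1.0), 3 * se)
  # unreachable constraint: expected minor homozygotes = 20 * 0.0025 << 5
  expect_error(simulate_genotype(20, maf = 0.05, seed = 5), "could not draw")
})

test_that("methylation follows the weighted min-max component model", {
  cfg <- sim_config(n_pairs = 200, a_G = 0.4, a_GxE = 0.1)
  set.seed(6)
  cov <- simulate_covariates(200)
  g <- simulate_genotype(200, 0.5)
  sim <- simulate_methylation(cfg, g, cov)
  expect_true(all(sim$y >= 0 & sim$y <= 1))
  # exact reconstruction from the returned truth components
  expect_equal(
    sim$y,
    0.4 * sim$g_term + cfg$a_E * sim$e_term + 0.1 * sim$gxe_term + 0.2 * sim$noise_term,
    tolerance = 1e-12
  )
  # degenerate weights: Y is exactly the scaled noise
  cfg0 <- sim_config(n_pairs = 200, a_G = 0, a_GxE = 0, a_error = 1)
  sim0 <- simulate_methylation(cfg0, g, cov)
  expect_equal(sim0$y, sim0$noise_term, tolerance = 1e-12)
  expect_equal(range(sim0$y), c(0, 1))
})

test_that("beta/M transforms are exact and invertible", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- c(0.01, 0.37, 0.99)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-9)
  expect_error(beta_to_m(1.2), "beta values")
  # boundary clipping keeps the transform finite
  expect_true(is.finite(beta_to_m(0)))
  expect_true(is.finite(beta_to_m(1)))
})

test_that("simulation is reproducible and co-twin exchangeable", {
  cfg <- sim_config(n_pairs = 50, a_G = 0.2, a_GxE = 0.1, seed = 7)
  a <- simulate_twin_replicate(cfg, seed = 7)
  b <- simulate_twin_replicate(cfg, seed = 7)
  expect_identical(a, b)
  # swapping twin labels leaves |difference| and mean statistics unchanged
  y <- a$methylation$y
  t1 <- y[a$methylation$twin == 1]
  t2 <- y[a$methylation$twin == 2]
  expect_equal(abs(t1 - t2), abs(t2 - t1))
  expect_equal((t1 + t2) / 2, (t2 + t1) / 2)
})

test_that("multi-locus genome has the advertised LD and truth wiring", {
  coh <- simulate_cohort_genome(
    n_pairs = 120, n_snps = 20, n_cpgs = 8,
    ld_block_size = 4, copy_noise = 0, seed = 8
  )
  expect_s3_class(coh, "twin_cohort")
  expect_setequal(unique(coh$snp_pos$chrom), c("chr1", "chr2"))
  # copy-noise 0: within-block dosages identical -> r^2 = 1
  expect_identical(coh$genotype[1, ], coh$genotype[2, ])
  # determinism
  coh2 <- simulate_cohort_genome(
    n_pairs = 120, n_snps = 20, n_cpgs = 8,
    ld_block_size = 4, copy_noise = 0, seed = 8
  )
  expect_identical(coh$genotype, coh2$genotype)
  expect_identical(coh$methylation, coh2$methylation)
  expect_equal(nrow(coh$truth), 8)
  expect_true(all(coh$truth$causal_snp %in% rownames(coh$genotype)))

  # ld_block_size 1: independent SNPs, low pairwise r^2
  ind <- simulate_cohort_genome(
    n_pairs = 300, n_snps = 10, n_cpgs = 2,
    ld_block_size = 1, seed = 9
  )
  r2 <- stats::cor(t(ind$genotype))^2
  expect_lt(max(r2[upper.tri(r2)]), 0.2)
})

test_that("unrelated cohort recovers per-genotype spread and guards groups", {
  d <- simulate_unrelated_cohort(1000, maf = 0.4, sds = c(1, 1.5, 2), seed = 10)
  sds <- tapply(d$y, d$genotype, stats::sd)
  ns <- table(d$genotype)
  for (g in c("0", "1", "2")) {
    target <- c(`0` = 1, `1` = 1.5, `2` = 2)[[g]]
    # chi-distribution SE of a sample SD: sd / sqrt(2 n)
    expect_lt(abs(sds[[g]] - target), 3 * target / sqrt(2 * ns[[g]]))
  }
  expect_error(
    simulate_unrelated_cohort(30, maf = 0.05, sds = c(1, 1, 1), seed = 11),
    "could not draw|fewer than"
  )
})

test_that("cohort TSV round trip preserves matrices", {
  coh <- make_tiny_cohort()
  dir <- withr::local_tempdir()
  paths <- write_cohort_tsv(coh, dir)
  g <- readr::read_tsv(paths[["genotype"]], show_col_types = FALSE)
  expect_equal(g$snp, rownames(coh$genotype))
  expect_equal(unlist(g[1, -1], use.names = FALSE), unname(coh$genotype[1, ]))
  m <- readr::read_tsv(paths[["methylation"]], show_col_types = FALSE)
  expect_equal(dim(m), dim(coh$methylation) + c(0, 1))
})
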