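test_that("residualization matches the closed-form normal-equations oracle", {
  coh <- make_tiny_cohort(n_pairs = 6, seed = 21)
  pt <- twinvqtl:::pair_table(coh$covariates)
  resp <- twinvqtl:::pair_response(coh, "cpg01")
  Xd <- cbind(1, pt$age, pt$sex, abs(pt$bmi_1 - pt$bmi_2),
    as.numeric(pt$smoking_1 != pt$smoking_2))
  Xm <- cbind(1, pt$age, pt$sex, (pt$bmi_1 + pt$bmi_2) / 2,
    as.numeric(pt$smoking_1 != pt$smoking_2))
  expect_equal(
    unname(residualize_difference(coh, "cpg01")),
    normal_equations_residuals(resp$abs_diff, Xd),
    tolerance = 1e-10
  )
  expect_equal(
    unname(residualize_mean(coh, "cpg01")),
    normal_equations_residuals(resp$mean, Xm),
    tolerance = 1e-10
  )
})

test_that("residuals have zero mean and respect twin-label symmetry", {
  coh <- make_tiny_cohort(n_pairs = 40, seed = 22)
  ra <- residualize_difference(coh, "cpg01")
  rm_ <- residualize_mean(coh, "cpg01")
  expect_lt(abs(mean(ra)), 1e-8)
  expect_lt(abs(mean(rm_)), 1e-8)
  expect_length(ra, 40)

  # swap twin labels: responses are symmetric, so residuals are identical
  # (only methylation assignment swaps; pair covariates age/sex shared and
  # BMI/smoking enter as |diff| / mean / discordance)
  swapped <- coh
  cov <- coh$covariates
  cov$twin <- ifelse(cov$twin == 1, 2L, 1L)
  swapped$covariates <- cov
  expect_equal(
    unname(residualize_difference(swapped, "cpg01")),
    unname(ra), tolerance = 1e-12
  )
  expect_equal(
    unname(residualize_mean(swapped, "cpg01")),
    unname(rm_), tolerance = 1e-12
  )
})

test_that("zero-discordance pairs give a constant-zero difference response", {
  coh <- make_tiny_cohort(n_pairs = 20, n_cpgs = 1, seed = 23)
  # make twin2 methylation identical to twin1
  cov <- coh$covariates
  id1 <- cov$individual_id[cov$twin == 1]
  id2 <- cov$individual_id[cov$twin == 2]
  coh$methylation[1, id2] <- coh$methylation[1, id1]
  ra <- residualize_difference(coh, rownames(coh$methylation)[1])
  expect_equal(unname(ra), rep(0, 20), tolerance = 1e-12)
})

test_that("missing methylation is refused", {
  coh <- make_tiny_cohort(n_pairs = 12, seed = 24)
  coh$methylation[1, 3] <- NA
  expect_error(residualize_difference(coh, "cpg01"), "missing")
})

test_that("each twins model matches the generic least-squares oracle", {
  set.seed(25)
  n <- 80
  res_abs <- stats::rnorm(n)
  res_mean <- stats::rnorm(n)
  res_mean[res_mean == 0] <- 0.1
  g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  designs <- list(
    Twins1 = list(y = res_abs, X = cbind(1, g)),
    Twins2 = list(y = res_abs^2, X = cbind(1, g)),
    Twins3 = list(y = res_abs / res_mean, X = cbind(1, g)),
    Twins4 = list(y = res_abs^2 / res_mean^2, X = cbind(1, g)),
    Twins5 = list(y = res_abs, X = cbind(1, g, res_mean)),
    Twins6 = list(y = res_abs^2, X = cbind(1, g, res_mean))
  )
  for (m in names(designs)) {
    got <- fit_twins_model(m, res_abs, res_mean, g)
    want <- normal_equations_slope_test(designs[[m]]$y, designs[[m]]$X)
    expect_equal(got$slope, unname(want$estimate), tolerance = 1e-10)
    expect_equal(got$se, unname(want$se), tolerance = 1e-10)
    expect_equal(got$p, unname(want$p), tolerance = 1e-10)
    # and against lm() as a second, independent route
    d <- data.frame(y = designs[[m]]$y, designs[[m]]$X[, -1, drop = FALSE])
    lf <- summary(stats::lm(y ~ ., data = d))$coefficients
    expect_equal(got$statistic, unname(lf[2, "t value"]), tolerance = 1e-10)
  }
})

test_that("ratio models drop zero-mean pairs and refuse tiny designs", {
  set.seed(26)
  res_abs <- stats::rnorm(30)
  res_mean <- stats::rnorm(30)
  res_mean[1:3] <- 0
  g <- rep(c(0, 1, 2), 10)
  got <- fit_twins_model("Twins3", res_abs, res_mean, g)
  expect_equal(got$n, 27)
  expect_equal(got$n_dropped, 3)
  expect_error(fit_twins_model("Twins1", res_abs, res_mean, rep(1, 30)), "constant")
  expect_error(
    fit_twins_model("Twins3", res_abs[1:12], c(rep(0, 8), res_mean[9:12]), g[1:12]),
    "fewer than 10"
  )
})

test_that("meQTL test is powered at a strong additive effect and refuses degenerate designs", {
  set.seed(27)
  cfg <- sim_config(n_pairs = 350, a_G = 0.4, a_GxE = 0)
  hits <- 0L
  for (r in 1:100) {
    rep <- simulate_twin_replicate(cfg)
    pt <- twinvqtl:::pair_table(rep$covariates)
    y1 <- rep$methylation$y[rep$methylation$twin == 1]
    y2 <- rep$methylation$y[rep$methylation$twin == 2]
    res <- twinvqtl:::residualize_pair_vectors(abs(y1 - y2), (y1 + y2) / 2, pt)
    if (fit_meqtl(res$res_mean, rep$genotype)$p < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 95)
  expect_error(fit_meqtl(stats::rnorm(20), rep(2, 20)), "constant")
})

test_that("conditional refit removes nothing real and matches its fast path", {
  set.seed(28)
  coh <- simulate_cohort_genome(
    n_pairs = 200, n_snps = 4, n_cpgs = 4,
    ld_block_size = 1, classes = c("meqtl", "vmeqtl"),
    a_G = 0.4, a_GxE = 0.25, seed = 29
  )
  tr <- coh$truth
  vme_cpg <- tr$cpg[tr$class == "vmeqtl"][1]
  vme_snp <- tr$causal_snp[tr$cpg == vme_cpg]
  cond <- refit_conditional_on_meqtl(coh, vme_cpg, vme_snp)
  fast <- refit_conditional_on_meqtl(coh, vme_cpg, vme_snp, method = "demean")
  # true GxE signal survives conditioning
  direct <- fit_twins_model(
    "Twins1",
    residualize_difference(coh, vme_cpg),
    genotype = coh$genotype[vme_snp, ]
  )
  # MZ co-twins share dosage, so removing the mean effect preserves the
  # within-pair difference: conditional result equals the direct test
  expect_equal(cond$p, direct$p, tolerance = 1e-8)
  expect_equal(fast$p, direct$p, tolerance = 1e-8)
  expect_lt(cond$p, 0.05)

  # SNP with ~zero marginal effect: adjusted values equal originals up to
  # a negligible slope
  null_cpg <- tr$cpg[tr$class == "vmeqtl"][2]
  null_snp <- setdiff(rownames(coh$genotype), tr$causal_snp[tr$cpg == null_cpg])[1]
  r <- refit_conditional_on_meqtl(coh, null_cpg, null_snp, method = "demean")
  expect_lt(abs(attr(r, "meqtl_slope")), 0.05)
})

test_that("extended covariate set also removes pair-mean BMI and cells", {
  coh <- make_tiny_cohort(n_pairs = 30, seed = 30)
  cov <- coh$covariates
  set.seed(30)
  cells <- simulate_cell_proportions(nrow(cov))
  coh$covariates <- dplyr::bind_cols(cov, cells[, c("naiveCD8T", "CD8T", "monocytes", "granulocytes")])
  r_ext <- residualize_difference(coh, "cpg01", covariate_set = "extended")
  pt <- twinvqtl:::pair_table(coh$covariates)
  bmi_mean <- (pt$bmi_1 + pt$bmi_2) / 2
  # residuals orthogonal to the extended regressor
  expect_lt(abs(sum(r_ext * bmi_mean)), 1e-8)
  # plain cohort mode does not remove it
  r_coh <- residualize_difference(coh, "cpg01", covariate_set = "cohort")
  expect_gt(abs(sum(r_coh * bmi_mean)), 1e-8)
})
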