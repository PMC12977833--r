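#' Simulation configuration for the twin methylation model
#'
#' The simulated methylation value of each twin individual is a convex
#' combination of four min-max-scaled components: an additive genetic term,
#' a composite environmental term, a genotype-by-smoking interaction term,
#' and a noise term,
#' \deqn{Y = a_G\,s(G) + a_E\,s(E) + a_{GxE}\,s(G \times smoking) + a_{err}\,s(\epsilon),}
#' where \eqn{s(\cdot)} rescales to `[0, 1]` over all twin individuals. The
#' four weights must sum to 1, so `Y` is itself a beta-scale value in
#' `[0, 1]`. The default error weight is 0.2 and the environmental weight is
#' derived as `1 - a_G - a_GxE - a_error`.
#'
#' @param n_pairs Number of MZ twin pairs (default 350).
#' @param a_G,a_GxE Weights of the additive genetic and interaction terms.
#' @param a_error Weight of the noise term (default 0.2).
#' @param a_E Weight of the environmental term; derived from the sum-to-one
#'   constraint when `NULL`.
#' @param noise_law Noise distribution: standard normal, chi-squared with
#'   1 df, or Gamma(shape = 2, scale = 0.5).
#' @param scale Output scale, `"beta"` or `"M"`.
#' @param maf Minor allele frequency of the simulated causal variant.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 350, a_G = 0, a_GxE = 0, a_error = 0.2,
                       a_E = NULL,
                       noise_law = c("normal", "chisq_df1", "gamma_2_half"),
                       scale = c("beta", "M"), maf = 0.5, seed = NULL) {
  noise_law <- match.arg(noise_law)
  scale <- match.arg(scale)
  if (n_pairs < 1) rlang::abort("n_pairs must be >= 1")
  if (a_G < 0 || a_GxE < 0 || a_error < 0) rlang::abort("weights must be nonnegative")
  if (is.null(a_E)) a_E <- 1 - a_G - a_GxE - a_error
  if (a_E < -1e-12) {
    rlang::abort("infeasible configuration: a_G + a_GxE + a_error exceeds 1")
  }
  a_E <- max(a_E, 0)
  tot <- a_G + a_GxE + a_E + a_error
  if (abs(tot - 1) > 1e-8) rlang::abort("weights must sum to 1")
  if (maf <= 0 || maf > 0.5) rlang::abort("maf must be in (0, 0.5]")
  structure(
    list(
      n_pairs = n_pairs, a_G = a_G, a_GxE = a_GxE, a_E = a_E,
      a_error = a_error, noise_law = noise_law, scale = scale,
      maf = maf, seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate per-twin covariates for an MZ cohort
#'
#' Age (Uniform(20, 70)) and sex (Bernoulli(0.5)) are shared within a pair.
#' Each pair is assigned a BMI regime — Normal(25, sd 1) for 80% of pairs,
#' Normal(25, sd 3) for the remaining 20% — and each twin's BMI is drawn
#' independently from the pair's regime. Smoking is Bernoulli(0.1) per twin,
#' so roughly 18% of pairs are smoking-discordant, the main source of
#' within-pair environmental variation.
#'
#' @param n_pairs Number of MZ pairs.
#' @param seed Optional integer seed.
#' @return Tibble with one row per twin: `pair_id`, `twin`, `individual_id`,
#'   `age`, `sex`, `bmi`, `smoking`.
#' @export
simulate_covariates <- function(n_pairs, seed = NULL) {
  if (length(n_pairs) != 1 || is.na(n_pairs) || n_pairs < 1) {
    rlang::abort("n_pairs must be a single integer >= 1")
  }
  n_pairs <- as.integer(n_pairs)
  if (!is.null(seed)) set.seed(seed)
  age <- stats::runif(n_pairs, 20, 70)
  sex <- stats::rbinom(n_pairs, 1, 0.5)
  bmi_sd <- ifelse(stats::runif(n_pairs) < 0.8, 1, 3)
  pair_id <- sprintf("pair%04d", seq_len(n_pairs))
  per_twin <- function(twin) {
    tibble::tibble(
      pair_id = pair_id,
      twin = twin,
      age = age,
      sex = sex,
      bmi = stats::rnorm(n_pairs, 25, bmi_sd),
      smoking = stats::rbinom(n_pairs, 1, 0.1)
    )
  }
  out <- dplyr::bind_rows(per_twin(1L), per_twin(2L))
  out <- dplyr::arrange(out, .data$pair_id, .data$twin)
  out$individual_id <- paste0(out$pair_id, "_", out$twin)
  dplyr::relocate(out, "pair_id", "twin", "individual_id")
}

#' Simulate a biallelic genotype for MZ pairs under Hardy-Weinberg
#'
#' Dosages (0/1/2, count of minor alleles) are drawn once per pair under
#' Hardy-Weinberg proportions. Draws are repeated until every genotype group
#' that is present holds at least `min_group` pairs — the QC rule applied to
#' real cohorts to guard against imprinting-like artefacts — or the retry
#' budget is exhausted.
#'
#' @param n_pairs Number of pairs.
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param seed Optional integer seed.
#' @param min_group Minimum pairs per genotype group (default 5).
#' @param max_tries Redraw budget before failing (default 1000).
#' @return Integer dosage vector of length `n_pairs`.
#' @export
simulate_genotype <- function(n_pairs, maf = 0.5, seed = NULL,
                              min_group = 5L, max_tries = 1000L) {
  if (maf <= 0 || maf > 0.5) rlang::abort("maf must be in (0, 0.5]")
  if (n_pairs < 1) rlang::abort("n_pairs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  for (i in seq_len(max_tries)) {
    g <- sample(0:2, n_pairs, replace = TRUE, prob = probs)
    counts <- tabulate(g + 1L, nbins = 3L)
    if (all(counts >= min_group)) {
      return(g)
    }
  }
  rlang::abort(sprintf(
    "could not draw a genotype with >= %d pairs per group in %d tries (n_pairs = %d, maf = %.3f; expected minor homozygotes = %.2f)",
    min_group, max_tries, n_pairs, maf, n_pairs * maf^2
  ))
}

# Composite environmental exposure: equal-weight sum of the scaled main
# effects (age, sex, BMI, smoking), rescaled to [0, 1]. Smoking additionally
# enters the interaction term on its own.
compose_environment <- function(covariates) {
  scale01(
    scale01(covariates$age) + covariates$sex +
      scale01(covariates$bmi) + covariates$smoking
  )
}

draw_noise <- function(n, noise_law) {
  switch(noise_law,
    normal = stats::rnorm(n),
    chisq_df1 = stats::rchisq(n, df = 1),
    gamma_2_half = stats::rgamma(n, shape = 2, scale = 0.5),
    rlang::abort("unknown noise law")
  )
}

#' Simulate methylation for a twin cohort at one CpG
#'
#' Generates per-twin methylation as the weighted sum of min-max-scaled
#' genetic, environmental, genotype-by-smoking and noise components (see
#' [sim_config()]). Scaling is computed over all `2 * n_pairs` twin
#' individuals. A constant component (zero range) is set to 0. On the `"M"`
#' scale the beta value is logit2-transformed via [beta_to_m()].
#'
#' @param config A [sim_config()].
#' @param genotype Per-pair dosage vector (length `n_pairs`).
#' @param covariates Per-twin covariate tibble from [simulate_covariates()].
#' @return Tibble with one row per twin: identifiers, `y` (on the requested
#'   scale), `y_beta`, and the scaled true components `g_term`, `e_term`,
#'   `gxe_term`, `noise_term`.
#' @export
simulate_methylation <- function(config, genotype, covariates) {
  stopifnot(inherits(config, "sim_config"))
  n_pairs <- length(genotype)
  if (nrow(covariates) != 2 * n_pairs) {
    rlang::abort("covariates and genotype are not conformable")
  }
  g_ind <- genotype[match(covariates$pair_id, unique(covariates$pair_id))]
  g_term <- scale01(g_ind)
  e_term <- compose_environment(covariates)
  gxe_term <- scale01(g_ind * covariates$smoking)
  noise_term <- scale01(draw_noise(nrow(covariates), config$noise_law))
  y_beta <- config$a_G * g_term + config$a_E * e_term +
    config$a_GxE * gxe_term + config$a_error * noise_term
  y <- if (config$scale == "M") beta_to_m(y_beta) else y_beta
  tibble::tibble(
    pair_id = covariates$pair_id,
    twin = covariates$twin,
    individual_id = covariates$individual_id,
    y = y, y_beta = y_beta,
    g_term = g_term, e_term = e_term,
    gxe_term = gxe_term, noise_term = noise_term
  )
}

#' Beta value to M value
#'
#' `M = log2(beta / (1 - beta))`. Boundary values are clipped into
#' `[eps, 1 - eps]` before the transform.
#'
#' @param beta Methylation fractions.
#' @param eps Clipping epsilon (default `1e-6`).
#' @return M values.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 - 1e-12 | beta > 1 + 1e-12, na.rm = TRUE)) {
    rlang::abort("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' M value to beta value
#'
#' Inverse of [beta_to_m()].
#'
#' @param m M values.
#' @return Beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Simulate one single-locus twin cohort replicate
#'
#' Convenience wrapper drawing covariates, a genotype satisfying the
#' group-size rule, and methylation, as one replicate of the simulation
#' study.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for the replicate.
#' @return A list with `covariates`, `genotype`, `methylation` (tibble from
#'   [simulate_methylation()]).
#' @export
simulate_twin_replicate <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covariates <- simulate_covariates(config$n_pairs)
  genotype <- simulate_genotype(config$n_pairs, config$maf)
  meth <- simulate_methylation(config, genotype, covariates)
  list(covariates = covariates, genotype = genotype, methylation = meth)
}

#' Simulate a multi-locus twin cohort with LD structure and labelled loci
#'
#' Builds a small synthetic genome for exercising the mapping pipeline:
#' SNPs are laid out in LD blocks on two chromosomes, with within-block
#' dosages copied from the block's index SNP and re-drawn per pair with
#' probability `copy_noise` (tuning the within-block r-squared). CpGs are
#' placed so each has a cis window containing one block; a labelled subset
#' of CpGs is wired to the central SNP of its block as a mean-effect locus
#' (`meqtl`), a variance-effect locus (`vmeqtl`, genotype-by-smoking
#' interaction), both (`dual`), or no effect (`null`).
#'
#' @param n_pairs Number of MZ pairs.
#' @param n_snps,n_cpgs Counts of SNPs and CpGs.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param copy_noise Per-pair probability a block member's dosage is
#'   re-drawn independently instead of copied from the index SNP.
#' @param classes Character vector recycled over CpGs giving each locus
#'   class: `"null"`, `"meqtl"`, `"vmeqtl"`, or `"dual"`.
#' @param a_G Additive weight used for `meqtl`/`dual` loci.
#' @param a_GxE Interaction weight used for `vmeqtl`/`dual` loci.
#' @param noise_law,scale Passed to [sim_config()].
#' @param maf Allele frequency for block index SNPs.
#' @param seed Integer seed.
#' @return A [twin_cohort()] with a `truth` table (`cpg`, `class`,
#'   `causal_snp`).
#' @export
simulate_cohort_genome <- function(n_pairs = 350, n_snps = 50, n_cpgs = 20,
                                   ld_block_size = 5, copy_noise = 0.05,
                                   classes = c("null", "meqtl", "vmeqtl", "dual"),
                                   a_G = 0.4, a_GxE = 0.25,
                                   noise_law = "normal", scale = "beta",
                                   maf = 0.3, seed = 1L) {
  stopifnot(n_pairs >= 1, n_snps >= 1, n_cpgs >= 1, ld_block_size >= 1)
  set.seed(seed)
  covariates <- simulate_covariates(n_pairs)

  n_blocks <- ceiling(n_snps / ld_block_size)
  block_of <- rep(seq_len(n_blocks), each = ld_block_size)[seq_len(n_snps)]
  # blocks alternate between two chromosomes; members 10 kb apart, blocks
  # 3 Mb apart so distinct blocks are never in the same cis window
  block_chrom <- rep(c("chr1", "chr2"), length.out = n_blocks)
  block_start <- 1e6 + (ceiling(seq_len(n_blocks) / 2) - 1) * 3e6
  within <- stats::ave(seq_len(n_snps), block_of, FUN = seq_along)
  snp_pos <- tibble::tibble(
    id = sprintf("snp%04d", seq_len(n_snps)),
    chrom = block_chrom[block_of],
    pos = as.integer(block_start[block_of] + (within - 1) * 1e4)
  )

  genotype <- matrix(0L, nrow = n_snps, ncol = n_pairs,
    dimnames = list(snp_pos$id, unique(covariates$pair_id))
  )
  index_snp <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    members <- which(block_of == b)
    idx <- members[ceiling(length(members) / 2)]
    index_snp[b] <- idx
    g0 <- simulate_genotype(n_pairs, maf = maf)
    genotype[idx, ] <- g0
    probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    for (m in setdiff(members, idx)) {
      flip <- stats::runif(n_pairs) < copy_noise
      g <- g0
      g[flip] <- sample(0:2, sum(flip), replace = TRUE, prob = probs)
      genotype[m, ] <- g
    }
  }

  # each CpG sits at the centre of one block, cycling over blocks
  cpg_block <- rep(seq_len(n_blocks), length.out = n_cpgs)
  cls <- rep(classes, length.out = n_cpgs)
  cpg_pos <- tibble::tibble(
    id = sprintf("cpg%04d", seq_len(n_cpgs)),
    chrom = block_chrom[cpg_block],
    pos = as.integer(block_start[cpg_block] + 5e4)
  )

  meth <- matrix(NA_real_, nrow = n_cpgs, ncol = nrow(covariates),
    dimnames = list(cpg_pos$id, covariates$individual_id)
  )
  truth <- vector("list", n_cpgs)
  for (j in seq_len(n_cpgs)) {
    causal <- index_snp[cpg_block[j]]
    aG <- if (cls[j] %in% c("meqtl", "dual")) a_G else 0
    aGxE <- if (cls[j] %in% c("vmeqtl", "dual")) a_GxE else 0
    cfg <- sim_config(
      n_pairs = n_pairs, a_G = aG, a_GxE = aGxE,
      noise_law = noise_law, scale = scale, maf = maf
    )
    sim <- simulate_methylation(cfg, genotype[causal, ], covariates)
    meth[j, ] <- sim$y[match(colnames(meth), sim$individual_id)]
    truth[[j]] <- tibble::tibble(
      cpg = cpg_pos$id[j], class = cls[j],
      causal_snp = snp_pos$id[causal], a_G = aG, a_GxE = aGxE
    )
  }

  twin_cohort(
    covariates = covariates, genotype = genotype, methylation = meth,
    snp_pos = snp_pos, cpg_pos = cpg_pos, scale = scale,
    truth = dplyr::bind_rows(truth)
  )
}

#' Simulate a cohort of unrelated individuals with per-genotype variances
#'
#' Phenotypes are drawn per genotype group as Normal(mean, sd) with
#' group-specific parameters, the layout used to study variance tests for
#' singletons (DRM, SVLM). Covariates are drawn as for twins but per
#' individual.
#'
#' @param n Number of individuals.
#' @param maf Allele frequency of the variant.
#' @param sds Length-3 vector of phenotype SDs for dosage 0/1/2.
#' @param means Length-3 vector of phenotype means for dosage 0/1/2.
#' @param seed Optional seed.
#' @param min_group Minimum individuals required in each present genotype
#'   group (default 3).
#' @return Tibble with `individual_id`, `genotype`, `y`, and covariates.
#' @export
simulate_unrelated_cohort <- function(n, maf = 0.3, sds = c(1, 1, 1),
                                      means = c(0, 0, 0), seed = NULL,
                                      min_group = 3L) {
  stopifnot(length(sds) == 3, length(means) == 3, all(sds > 0))
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotype(n, maf = maf, min_group = min_group)
  counts <- tabulate(g + 1L, nbins = 3L)
  if (any(counts > 0 & counts < min_group)) {
    rlang::abort(sprintf("genotype group with fewer than %d individuals", min_group))
  }
  y <- stats::rnorm(n, mean = means[g + 1L], sd = sds[g + 1L])
  cov <- simulate_covariates(n)
  cov <- dplyr::filter(cov, .data$twin == 1)
  tibble::tibble(
    individual_id = sprintf("ind%05d", seq_len(n)),
    genotype = g, y = y,
    age = cov$age, sex = cov$sex, bmi = cov$bmi, smoking = cov$smoking
  )
}

#' Simulate blood cell proportions
#'
#' Draws per-individual cell-type proportions (granulocytes, CD4T, CD8T,
#' naive CD8T, B, NK, monocytes) from independent Gamma variables with
#' realistic whole-blood means, normalised to sum to 1.
#'
#' @param n Number of individuals.
#' @param seed Optional seed.
#' @return Tibble with one nonnegative column per cell type, rows summing
#'   to 1.
#' @export
simulate_cell_proportions <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- c(
    granulocytes = 0.55, CD4T = 0.15, CD8T = 0.08, naiveCD8T = 0.04,
    B = 0.05, NK = 0.05, monocytes = 0.08
  )
  draws <- vapply(means, function(m) stats::rgamma(n, shape = 20 * m, rate = 20), numeric(n))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- names(means)
  tibble::as_tibble(draws / rowSums(draws))
}

#' Simulate a per-individual twin dataset for interaction testing
#'
#' One replicate of the twin simulation augmented with what the two-stage
#' interaction test consumes: technical batch labels (with a small additive
#' batch effect, giving the random intercept something to estimate), cell
#' proportions, and the myeloid-to-lymphoid ratio. The methylation `y`
#' follows the component model of [sim_config()].
#'
#' @param config A [sim_config()].
#' @param n_batches Number of technical batches (default 8).
#' @param batch_sd SD of the additive batch effect on `y` (default 0.02).
#' @param seed Optional seed.
#' @return Per-individual tibble: `y`, `genotype`, `family`, `batch`,
#'   `age`, `sex`, `bmi`, `smoking`, cell columns, `MLR`.
#' @export
simulate_gxe_cohort <- function(config, n_batches = 8, batch_sd = 0.02,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covariates <- simulate_covariates(config$n_pairs)
  genotype <- simulate_genotype(config$n_pairs, config$maf)
  meth <- simulate_methylation(config, genotype, covariates)
  n_ind <- nrow(covariates)
  batch <- sample(seq_len(n_batches), n_ind, replace = TRUE)
  b_eff <- stats::rnorm(n_batches, 0, batch_sd)
  cells <- simulate_cell_proportions(n_ind)
  out <- tibble::tibble(
    individual_id = covariates$individual_id,
    family = covariates$pair_id,
    batch = factor(batch),
    genotype = genotype[match(covariates$pair_id, unique(covariates$pair_id))],
    y = meth$y + b_eff[batch],
    age = covariates$age, sex = covariates$sex,
    bmi = covariates$bmi, smoking = covariates$smoking
  )
  out <- dplyr::bind_cols(out, cells)
  out$MLR <- compute_mlr(out)
  out
}
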