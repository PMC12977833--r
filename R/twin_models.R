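# Intra-pair residualization and the six twin variance-QTL models.

# Build the per-pair design matrix for a covariate set. `which` selects the
# response-specific covariate layout:
#   difference: age + sex + |diff(BMI)| + diff(smoking)  [simulation mode]
#   mean:       age + sex + mean(BMI)   + diff(smoking)
# Cohort mode appends per-pair differences/means of cell proportions and a
# batch-concordance indicator, and drops sex when it is constant (e.g. an
# all-female cohort). The extended mode is the sensitivity layout: cohort
# covariates plus, for the difference response, within-pair means of BMI
# and of the cell proportions.
pair_design <- function(cohort, which = c("difference", "mean"),
                        covariate_set = c("simulation", "cohort", "extended")) {
  which <- match.arg(which)
  covariate_set <- match.arg(covariate_set)
  cov <- cohort$covariates
  pt <- pair_table(cov)
  X <- cbind(
    intercept = 1,
    age = pt$age,
    sex = pt$sex,
    bmi = if (which == "difference") abs(pt$bmi_1 - pt$bmi_2) else (pt$bmi_1 + pt$bmi_2) / 2,
    smoking_diff = as.numeric(pt$smoking_1 != pt$smoking_2)
  )
  if (covariate_set %in% c("cohort", "extended")) {
    cell_cols <- intersect(
      c("naiveCD8T", "CD8T", "monocytes", "granulocytes"), names(cov)
    )
    c1 <- c2 <- NULL
    if (length(cell_cols) > 0) {
      c1 <- as.matrix(dplyr::filter(cov, .data$twin == 1)[, cell_cols])
      c2 <- as.matrix(dplyr::filter(cov, .data$twin == 2)[, cell_cols])
      cells <- if (which == "difference") abs(c1 - c2) else (c1 + c2) / 2
      colnames(cells) <- paste0("cell_", cell_cols)
      X <- cbind(X, cells)
    }
    if ("batch" %in% names(cov)) {
      X <- cbind(X, batch_diff = as.numeric(pt$batch_1 != pt$batch_2))
    }
    if (covariate_set == "extended" && which == "difference") {
      X <- cbind(X, bmi_mean = (pt$bmi_1 + pt$bmi_2) / 2)
      if (length(cell_cols) > 0) {
        cm <- (c1 + c2) / 2
        colnames(cm) <- paste0("cellmean_", cell_cols)
        X <- cbind(X, cm)
      }
    }
    if (stats::var(pt$sex) == 0) X <- X[, colnames(X) != "sex", drop = FALSE]
  }
  rownames(X) <- pt$pair_id
  X
}

# Per-pair response vectors for one CpG: |twin1 - twin2| and (twin1+twin2)/2,
# aligned to pair_table() order.
pair_response <- function(cohort, cpg) {
  y <- cohort$methylation[cpg, ]
  if (anyNA(y)) {
    rlang::abort(sprintf("CpG %s has missing values; probes with missing values are excluded", cpg))
  }
  cov <- cohort$covariates
  pairs <- pair_table(cov)$pair_id
  id1 <- cov$individual_id[match(paste0(pairs, ":1"), paste0(cov$pair_id, ":", cov$twin))]
  id2 <- cov$individual_id[match(paste0(pairs, ":2"), paste0(cov$pair_id, ":", cov$twin))]
  y1 <- y[match(id1, colnames(cohort$methylation))]
  y2 <- y[match(id2, colnames(cohort$methylation))]
  list(abs_diff = abs(y1 - y2), mean = (y1 + y2) / 2, pair_id = pairs)
}

#' Residualize the intra-pair absolute methylation difference
#'
#' Regresses `|twin1 - twin2|` methylation on the pair-level covariates and
#' returns the OLS residuals. In `"simulation"` mode the covariates are age,
#' sex, the absolute within-pair BMI difference and a smoking-discordance
#' indicator (0 = concordant, 1 = discordant); in `"cohort"` mode within-pair
#' differences of estimated cell proportions and a batch-concordance
#' indicator are appended (sex is dropped if constant).
#'
#' @param cohort A [twin_cohort()].
#' @param cpg CpG identifier (rowname of the methylation matrix).
#' @param covariate_set `"simulation"`, `"cohort"`, or `"extended"` (the
#'   sensitivity layout adding within-pair mean BMI and mean cell
#'   proportions to the difference model).
#' @return Named numeric vector of per-pair residuals (zero mean).
#' @export
residualize_difference <- function(cohort, cpg,
                                   covariate_set = c("simulation", "cohort", "extended")) {
  covariate_set <- match.arg(covariate_set)
  resp <- pair_response(cohort, cpg)
  X <- pair_design(cohort, "difference", covariate_set)
  r <- ols_residuals(resp$abs_diff, X)
  names(r) <- resp$pair_id
  r
}

#' Residualize the within-pair mean methylation
#'
#' As [residualize_difference()], but the response is `(twin1 + twin2) / 2`
#' and BMI/cell covariates enter as within-pair means.
#'
#' @inheritParams residualize_difference
#' @return Named numeric vector of per-pair residuals (zero mean).
#' @export
residualize_mean <- function(cohort, cpg,
                             covariate_set = c("simulation", "cohort", "extended")) {
  covariate_set <- match.arg(covariate_set)
  resp <- pair_response(cohort, cpg)
  X <- pair_design(cohort, "mean", covariate_set)
  r <- ols_residuals(resp$mean, X)
  names(r) <- resp$pair_id
  r
}

# Internal: residualize directly from per-pair responses + covariate tibble
# (used by the simulation engine where no full cohort object exists).
residualize_pair_vectors <- function(abs_diff, mean_level, pairs_cov) {
  Xd <- cbind(1, pairs_cov$age, pairs_cov$sex,
    abs(pairs_cov$bmi_1 - pairs_cov$bmi_2),
    as.numeric(pairs_cov$smoking_1 != pairs_cov$smoking_2)
  )
  Xm <- cbind(1, pairs_cov$age, pairs_cov$sex,
    (pairs_cov$bmi_1 + pairs_cov$bmi_2) / 2,
    as.numeric(pairs_cov$smoking_1 != pairs_cov$smoking_2)
  )
  list(
    res_abs = ols_residuals(abs_diff, Xd),
    res_mean = ols_residuals(mean_level, Xm)
  )
}

twins_model_ids <- function() paste0("Twins", 1:6)

#' Fit one of the six twin variance-QTL models
#'
#' The six models regress transformations of the residualized intra-pair
#' absolute difference (`res_abs`) on the pair genotype dosage, optionally
#' involving the residualized within-pair mean (`res_mean`):
#'
#' * `Twins1`: `res_abs ~ G`
#' * `Twins2`: `res_abs^2 ~ G`
#' * `Twins3`: `res_abs / res_mean ~ G`
#' * `Twins4`: `res_abs^2 / res_mean^2 ~ G`
#' * `Twins5`: `res_abs ~ G + res_mean`
#' * `Twins6`: `res_abs^2 ~ G + res_mean`
#'
#' Genotype is coded additively (dosage) by default. For the ratio models
#' (Twins3/4), pairs with `res_mean == 0` are dropped and counted. The
#' genotype slope is tested two-sided against the t distribution with the
#' residual degrees of freedom.
#'
#' @param model_id One of `"Twins1"` .. `"Twins6"`.
#' @param res_abs,res_mean Per-pair residual vectors from
#'   [residualize_difference()] / [residualize_mean()].
#' @param genotype Per-pair dosage vector.
#' @param genotype_coding `"additive"` (dosage as a single regressor) or
#'   `"factor"` (genotype-group dummies; the reported slope/test is the
#'   first contrast's, with the model F-test p-value).
#' @return One-row tibble: `model`, `slope`, `se`, `statistic`, `p`, `n`,
#'   `n_dropped`.
#' @export
fit_twins_model <- function(model_id, res_abs, res_mean = NULL, genotype,
                            genotype_coding = c("additive", "factor")) {
  genotype_coding <- match.arg(genotype_coding)
  if (!model_id %in% twins_model_ids()) {
    rlang::abort("model_id must be one of Twins1..Twins6")
  }
  needs_mean <- model_id %in% c("Twins3", "Twins4", "Twins5", "Twins6")
  if (needs_mean && is.null(res_mean)) {
    rlang::abort(sprintf("%s requires res_mean", model_id))
  }
  if (length(unique(genotype)) < 2) {
    rlang::abort("genotype is constant: degenerate design")
  }
  n0 <- length(res_abs)
  keep <- rep(TRUE, n0)
  y <- switch(model_id,
    Twins1 = res_abs,
    Twins2 = res_abs^2,
    Twins3 = {
      keep <- res_mean != 0
      res_abs[keep] / res_mean[keep]
    },
    Twins4 = {
      keep <- res_mean != 0
      res_abs[keep]^2 / res_mean[keep]^2
    },
    Twins5 = res_abs,
    Twins6 = res_abs^2
  )
  g <- genotype[keep]
  n <- sum(keep)
  if (n < 10) rlang::abort("fewer than 10 usable pairs")
  if (length(unique(g)) < 2) rlang::abort("genotype constant among usable pairs")
  gX <- if (genotype_coding == "additive") {
    cbind(genotype = g)
  } else {
    stats::model.matrix(~ factor(g))[, -1, drop = FALSE]
  }
  X <- cbind(intercept = 1, gX)
  if (model_id %in% c("Twins5", "Twins6")) {
    X <- cbind(X, res_mean = res_mean[keep])
  }
  fit <- ols_slope_test(y, X, coef = 2L)
  tibble::tibble(
    model = model_id,
    slope = fit$estimate, se = fit$se, statistic = fit$statistic,
    p = fit$p, n = n, n_dropped = n0 - n
  )
}

#' Fit all six twin models at once
#'
#' @inheritParams fit_twins_model
#' @param models Character vector of model ids (default all six).
#' @return Tibble with one row per model.
#' @export
fit_all_twins_models <- function(res_abs, res_mean, genotype,
                                 models = twins_model_ids()) {
  purrr::map_dfr(models, fit_twins_model,
    res_abs = res_abs, res_mean = res_mean, genotype = genotype
  )
}

#' Mean-level methylation QTL test
#'
#' Regresses the residualized within-pair mean methylation on the pair
#' genotype dosage — the mean-effect (meQTL) analogue of the variance tests.
#'
#' @param res_mean Per-pair residualized mean methylation.
#' @param genotype Per-pair dosage vector.
#' @return One-row tibble as in [fit_twins_model()], with `model = "meQTL"`.
#' @export
fit_meqtl <- function(res_mean, genotype) {
  if (length(unique(genotype)) < 2) {
    rlang::abort("genotype is constant: degenerate design")
  }
  fit <- ols_slope_test(res_mean, cbind(intercept = 1, genotype = genotype), 2L)
  tibble::tibble(
    model = "meQTL",
    slope = fit$estimate, se = fit$se, statistic = fit$statistic,
    p = fit$p, n = length(res_mean), n_dropped = 0L
  )
}

#' Retest a variance signal after removing the mean genotype effect
#'
#' For SNPs called as both mean- and variance-QTL for the same CpG, the
#' mean effect is regressed out of each twin's methylation with a family
#' random-intercept model (`DNAm ~ (1|pair) + dosage`), the intra-pair
#' absolute difference of the adjusted values is recomputed, residualized,
#' and retested against genotype (Twins1). Because MZ co-twins share
#' genotype, subtracting the fitted genotype effect shifts both twins of a
#' pair equally, so the within-pair difference is preserved by construction;
#' the refit verifies the variance signal is not an artefact of the mean
#' model.
#'
#' @param cohort A [twin_cohort()].
#' @param cpg,snp Identifiers of the CpG and the dual-signal SNP.
#' @param covariate_set Covariate layout for the residualization.
#' @param method `"reml"` for the lme4 mixed fit, `"demean"` for the exact
#'   fast path that estimates the dosage effect from pair means.
#' @return One-row tibble as [fit_twins_model()], with attribute
#'   `meqtl_slope` (the removed mean effect).
#' @export
refit_conditional_on_meqtl <- function(cohort, cpg, snp,
                                       covariate_set = c("simulation", "cohort"),
                                       method = c("reml", "demean")) {
  covariate_set <- match.arg(covariate_set)
  method <- match.arg(method)
  y <- cohort$methylation[cpg, ]
  if (anyNA(y)) rlang::abort("CpG has missing values")
  cov <- cohort$covariates
  ord <- match(colnames(cohort$methylation), cov$individual_id)
  fam <- cov$pair_id[ord]
  g_pair <- cohort$genotype[snp, ]
  g <- g_pair[match(fam, colnames(cohort$genotype))]
  if (length(unique(g)) < 2) rlang::abort("SNP dosage is constant")
  slope <- if (method == "reml") {
    fit <- lme4::lmer(y ~ g + (1 | fam), REML = TRUE)
    unname(lme4::fixef(fit)["g"])
  } else {
    # pair means carry all genotype information for an MZ-shared dosage
    pm <- tapply(y, fam, mean)
    gg <- g_pair[names(pm)]
    unname(stats::coef(stats::lm(pm ~ gg))[2])
  }
  adj <- cohort
  adj$methylation[cpg, ] <- y - slope * g
  adj$scale <- "M" # adjusted values may leave [0,1]; container check relaxed
  class(adj) <- "twin_cohort"
  res_abs <- residualize_difference(adj, cpg, covariate_set)
  out <- fit_twins_model("Twins1", res_abs, genotype = g_pair)
  attr(out, "meqtl_slope") <- slope
  out
}
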