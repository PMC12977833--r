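# Two-stage gene-environment interaction testing at the individual-twin
# level.

gxe_modifiers <- function() {
  c("bmi", "smoking", "naiveCD8T", "CD8T", "granulocytes", "monocytes", "MLR")
}

#' Myeloid-to-lymphoid ratio
#'
#' `MLR = monocytes / (B + CD8T + CD4T + NK)`. A zero denominator yields a
#' missing value.
#'
#' @param cells Data frame with nonnegative columns `monocytes`, `B`,
#'   `CD8T`, `CD4T`, `NK`.
#' @return Numeric vector of per-individual ratios.
#' @export
compute_mlr <- function(cells) {
  need <- c("monocytes", "B", "CD8T", "CD4T", "NK")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) {
    rlang::abort(paste0("cells lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(as.matrix(cells[, need]) < 0, na.rm = TRUE)) {
    rlang::abort("cell proportions must be nonnegative")
  }
  denom <- cells$B + cells$CD8T + cells$CD4T + cells$NK
  out <- cells$monocytes / denom
  out[denom == 0] <- NA_real_
  out
}

#' Stage-1 residualization for interaction testing
#'
#' Fits a linear mixed model of per-individual methylation on age and the
#' background environmental covariates, with random intercepts for family
#' (twin pair) and technical batch, and returns the conditional residuals.
#' The modifier under test is excluded from the fixed effects, and so is
#' MLR (it is a ratio of cell components already represented); when the
#' modifier of interest *is* MLR, stage 1 adjusts for age, BMI, smoking and
#' the four cell components instead. Passing the modifier itself among the
#' covariates is refused (leakage guard).
#'
#' @param data Per-individual tibble with columns `y` (methylation),
#'   `family`, `batch`, `age`, and the modifier columns
#'   `bmi`, `smoking`, `naiveCD8T`, `CD8T`, `granulocytes`, `monocytes`
#'   (and `MLR`, or the raw `B`, `CD4T`, `NK` columns to derive it).
#' @param modifier The stage-2 modifier of interest (excluded here); one of
#'   `r paste(gxe_modifiers(), collapse = ", ")`.
#' @param method `"reml"` for the lme4 random-intercept fit; `"ols"` forces
#'   the fixed-effects fallback (family and batch as fixed factors), which
#'   is also used automatically if the mixed fit is singular or fails.
#' @return Numeric residual vector with attribute `fallback` (TRUE when the
#'   fixed-effects path was used).
#' @export
stage1_residualize <- function(data, modifier, method = c("reml", "ols")) {
  method <- match.arg(method)
  modifier <- match.arg(modifier, gxe_modifiers())
  data <- tibble::as_tibble(data)
  covs <- if (modifier == "MLR") {
    c("bmi", "smoking", "naiveCD8T", "CD8T", "granulocytes", "monocytes")
  } else {
    setdiff(gxe_modifiers(), c(modifier, "MLR"))
  }
  need <- c("y", "family", "batch", "age", covs)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    rlang::abort(paste0("data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  fixed <- paste(c("age", covs), collapse = " + ")
  fallback <- FALSE
  res <- NULL
  if (method == "reml") {
    f <- stats::as.formula(paste0("y ~ ", fixed, " + (1 | family) + (1 | batch)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(lme4::lmer(f, data = data, REML = TRUE))),
      error = function(e) NULL
    )
    # singular fits are kept: a zero-variance component reduces exactly to
    # OLS in that term, which is the intended degenerate behaviour
    if (!is.null(fit)) res <- stats::residuals(fit)
  }
  if (is.null(res)) {
    fallback <- TRUE
    n <- nrow(data)
    terms <- c("age", covs)
    for (gf in c("family", "batch")) {
      k <- length(unique(data[[gf]]))
      if (k >= 2 && k < n) terms <- c(terms, paste0("factor(", gf, ")"))
    }
    f <- stats::as.formula(paste0("y ~ ", paste(terms, collapse = " + ")))
    res <- stats::residuals(stats::lm(f, data = data))
  }
  res <- as.numeric(res)
  attr(res, "fallback") <- fallback
  res
}

#' Stage-2 interaction test
#'
#' OLS of the stage-1 residuals on the variant dosage, the modifier, and
#' their product; the reported test is the two-sided t-test of the
#' interaction slope.
#'
#' When `family` is supplied, the within-pair mean of the modifier is added
#' as an extra main effect (a within/between decomposition). The stage-1
#' family random intercept shrinks but does not eliminate the between-pair
#' component of the modifier's main effect, so omitting the pair mean
#' leaves a clustered residual term that inflates the interaction test;
#' including it restores nominal calibration (see the package vignette).
#'
#' @param residuals Stage-1 residual vector (per individual).
#' @param genotype Per-individual dosage vector (co-twins share their
#'   pair's dosage).
#' @param modifier Per-individual modifier values.
#' @param modifier_name Label recorded in the output.
#' @param family Optional per-individual family (pair) identifiers.
#' @return One-row tibble: `modifier`, `beta_gxe`, `se`, `statistic`, `p`,
#'   `n`.
#' @export
test_interaction <- function(residuals, genotype, modifier,
                             modifier_name = "modifier", family = NULL) {
  stopifnot(length(residuals) == length(genotype),
            length(residuals) == length(modifier))
  if (length(unique(genotype)) < 2) rlang::abort("genotype is constant")
  if (length(unique(modifier)) < 2) rlang::abort("modifier is constant")
  X <- cbind(
    intercept = 1, genotype = genotype, modifier = modifier
  )
  if (!is.null(family)) {
    pm <- stats::ave(modifier, family)
    # aliased when the modifier is pair-constant; the pivoted QR drops it
    X <- cbind(X, modifier_pair_mean = pm)
  }
  X <- cbind(X, interaction = genotype * modifier)
  fit <- ols_slope_test(as.numeric(residuals), X, coef = ncol(X))
  tibble::tibble(
    modifier = modifier_name,
    beta_gxe = fit$estimate, se = fit$se, statistic = fit$statistic,
    p = fit$p, n = length(residuals)
  )
}

#' Run the two-stage GxE scan over associations and modifiers
#'
#' For each (CpG, SNP) association and each modifier, runs
#' [stage1_residualize()] on the per-individual methylation and
#' [test_interaction()] on the residuals, then applies Benjamini-Hochberg
#' FDR across all association x modifier tests (optionally within each
#' modifier).
#'
#' @param data Per-individual tibble as in [stage1_residualize()], with the
#'   methylation for one CpG in `y` and the dosage in `genotype` — or a
#'   function `(cpg, snp) -> tibble` when scanning many associations.
#' @param associations Tibble with columns `cpg` and `snp`.
#' @param modifiers Modifier names (default all seven).
#' @param fdr_pool `"global"` (default) or `"per_modifier"`.
#' @return Tibble: one row per association x modifier with `q` appended.
#' @export
gxe_scan <- function(data, associations, modifiers = gxe_modifiers(),
                     fdr_pool = c("global", "per_modifier")) {
  fdr_pool <- match.arg(fdr_pool)
  get_data <- if (is.function(data)) data else function(cpg, snp) data
  out <- purrr::map_dfr(seq_len(nrow(associations)), function(i) {
    d <- get_data(associations$cpg[i], associations$snp[i])
    if (!"MLR" %in% names(d) && all(c("B", "CD4T", "NK") %in% names(d))) {
      d$MLR <- compute_mlr(d)
    }
    purrr::map_dfr(modifiers, function(mod) {
      res <- stage1_residualize(d, mod)
      dplyr::mutate(
        test_interaction(res, d$genotype, d[[mod]],
          modifier_name = mod, family = d$family
        ),
        cpg = associations$cpg[i], snp = associations$snp[i],
        stage1_fallback = attr(res, "fallback")
      )
    })
  })
  out <- dplyr::relocate(out, "cpg", "snp", "modifier")
  if (fdr_pool == "global") {
    out$q <- stats::p.adjust(out$p, method = "BH")
  } else {
    out <- out |>
      dplyr::group_by(.data$modifier) |>
      dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  out
}

#' Intersect interaction results across cohorts
#'
#' Returns the interactions significant (`q < q_threshold`) in both result
#' tables with matching (CpG, SNP, modifier) keys. Sign concordance of the
#' interaction slope is required only when `require_sign = TRUE`.
#'
#' @param results_a,results_b Tibbles with `cpg`, `snp`, `modifier`,
#'   `beta_gxe`, `q`.
#' @param q_threshold Significance cutoff (default 0.05).
#' @param require_sign Require concordant interaction-slope signs.
#' @return Tibble of shared significant interactions with suffixed columns.
#' @export
intersect_interactions <- function(results_a, results_b, q_threshold = 0.05,
                                   require_sign = FALSE) {
  keys <- c("cpg", "snp", "modifier")
  a <- dplyr::filter(results_a, .data$q < q_threshold)
  b <- dplyr::filter(results_b, .data$q < q_threshold)
  out <- dplyr::inner_join(a, b, by = keys, suffix = c("_a", "_b"))
  if (require_sign && nrow(out) > 0) {
    out <- dplyr::filter(out, sign(.data$beta_gxe_a) == sign(.data$beta_gxe_b))
  }
  out
}
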