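# Simulation study: FPR / discovery-rate surfaces for the six twin models.

# One simulation replicate -> p-values of the requested models (+ optionally
# the mean-level test). Kept lean: everything is plain vectors and QR fits.
replicate_pvalues <- function(config, models = twins_model_ids(),
                              include_meqtl = FALSE) {
  covariates <- simulate_covariates(config$n_pairs)
  genotype <- simulate_genotype(config$n_pairs, config$maf)
  meth <- simulate_methylation(config, genotype, covariates)
  pt <- pair_table(covariates)
  y1 <- meth$y[meth$twin == 1][match(pt$pair_id, meth$pair_id[meth$twin == 1])]
  y2 <- meth$y[meth$twin == 2][match(pt$pair_id, meth$pair_id[meth$twin == 2])]
  res <- residualize_pair_vectors(abs(y1 - y2), (y1 + y2) / 2, pt)
  fits <- fit_all_twins_models(res$res_abs, res$res_mean, genotype, models)
  if (include_meqtl) {
    fits <- dplyr::bind_rows(fits, fit_meqtl(res$res_mean, genotype))
  }
  fits[, c("model", "p")]
}

#' Run the simulation evaluation grid
#'
#' For each `(a_G, a_GxE)` cell, noise law and methylation scale, simulates
#' `n_reps` independent twin cohorts, fits the six twin models, and
#' tabulates the proportion of replicates with a nominally significant
#' (`p < alpha`) genotype effect — the false positive rate when
#' `a_GxE = 0` and the discovery rate otherwise. The error weight is fixed
#' at `a_error` (default 0.2) and the environmental weight absorbs the
#' remainder of the sum-to-one constraint; infeasible cells
#' (`a_G + a_GxE + a_error > 1`) are skipped with a warning. Per-cell seeds
#' are derived deterministically from `seed`, so results do not depend on
#' execution order.
#'
#' @param grid Data frame with columns `a_G` and `a_GxE` (one row per cell).
#' @param noise_laws Character vector of noise laws to cross with the grid.
#' @param scales Methylation scales to cross (`"beta"`, `"M"`).
#' @param n_pairs Pairs per replicate (default 350).
#' @param n_reps Replicates per cell (default 1000).
#' @param alpha Nominal significance level (default 0.05).
#' @param models Model ids to fit.
#' @param seed Master seed.
#' @return Tibble of class `vqtl_grid`: one row per cell x model with
#'   `discovery_rate` and its Monte-Carlo standard error `mc_se`.
#' @export
run_grid <- function(grid, noise_laws = "normal", scales = "beta",
                     n_pairs = 350, n_reps = 1000, alpha = 0.05,
                     models = twins_model_ids(), seed = 1L) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("a_G", "a_GxE") %in% names(grid)))
  if (n_reps < 1) rlang::abort("n_reps must be >= 1")
  cells <- tidyr::expand_grid(grid, noise_law = noise_laws, scale = scales)
  feasible <- cells$a_G + cells$a_GxE + 0.2 <= 1 + 1e-12
  if (any(!feasible)) {
    rlang::warn(sprintf("skipping %d infeasible grid cell(s) (a_E < 0)", sum(!feasible)))
    cells <- cells[feasible, ]
  }
  cell_seeds <- derive_seeds(seed, nrow(cells))
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    cfg <- sim_config(
      n_pairs = n_pairs, a_G = cell$a_G, a_GxE = cell$a_GxE,
      noise_law = cell$noise_law, scale = cell$scale
    )
    rep_seeds <- derive_seeds(cell_seeds[i], n_reps)
    ps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      set.seed(rep_seeds[r])
      dplyr::mutate(replicate_pvalues(cfg, models), rep = r)
    })
    ps |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(
        n_reps = dplyr::n(),
        discovery_rate = mean(.data$p < alpha),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        a_G = cell$a_G, a_GxE = cell$a_GxE,
        noise_law = cell$noise_law, scale = cell$scale,
        mc_se = sqrt(.data$discovery_rate * (1 - .data$discovery_rate) / .data$n_reps)
      )
  })
  out <- dplyr::relocate(out, "a_G", "a_GxE", "noise_law", "scale", "model")
  class(out) <- c("vqtl_grid", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_pairs") <- n_pairs
  out
}

#' The coefficient grids used by the simulation study
#'
#' `"paper"` is the full 12 x 12 grid of additive and interaction weights
#' `{0, 0.005, 0.01, 0.03, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4}`
#' (infeasible combinations are skipped by [run_grid()]); `"ci"` is a
#' reduced grid suitable for routine checking.
#'
#' @param which `"paper"` or `"ci"`.
#' @return Tibble with columns `a_G`, `a_GxE`.
#' @export
coefficient_grid <- function(which = c("ci", "paper")) {
  which <- match.arg(which)
  if (which == "paper") {
    v <- c(0, 0.005, 0.01, 0.03, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4)
    tidyr::expand_grid(a_G = v, a_GxE = v)
  } else {
    tidyr::expand_grid(a_G = c(0, 0.1, 0.3), a_GxE = c(0, 0.05, 0.1, 0.2))
  }
}

#' Summarise an evaluation grid into qualitative findings
#'
#' Flags, per cell group, (i) null calibration: models whose false positive
#' rate under `a_GxE = 0` stays within three Monte-Carlo standard errors of
#' the nominal level are `"calibrated"`, others `"inflated"`; (ii) pairwise
#' power comparisons between Twins1 and each other model at `a_GxE > 0`
#' cells, flagged only when the difference exceeds twice the combined MC
#' error; (iii) a monotonicity check of discovery rate in `a_GxE` per model.
#'
#' @param table A `vqtl_grid` from [run_grid()].
#' @return List with tibbles `calibration`, `power_comparisons`,
#'   `monotonicity`.
#' @export
compare_models <- function(table) {
  alpha <- attr(table, "alpha") %||% 0.05
  null_se <- sqrt(alpha * (1 - alpha) / table$n_reps)
  calibration <- table |>
    dplyr::filter(.data$a_GxE == 0) |>
    dplyr::mutate(
      status = ifelse(.data$discovery_rate <= alpha + 3 * sqrt(alpha * (1 - alpha) / .data$n_reps),
        "calibrated", "inflated"
      )
    ) |>
    dplyr::select("a_G", "noise_law", "scale", "model", "discovery_rate", "status")

  power_cells <- dplyr::filter(table, .data$a_GxE > 0)
  power_comparisons <- if (nrow(power_cells) > 0) {
    ref <- dplyr::filter(power_cells, .data$model == "Twins1") |>
      dplyr::select("a_G", "a_GxE", "noise_law", "scale",
        rate_twins1 = "discovery_rate", se_twins1 = "mc_se"
      )
    power_cells |>
      dplyr::filter(.data$model != "Twins1") |>
      dplyr::inner_join(ref, by = c("a_G", "a_GxE", "noise_law", "scale")) |>
      dplyr::mutate(
        diff = .data$rate_twins1 - .data$discovery_rate,
        flag = dplyr::case_when(
          .data$diff > 2 * (.data$mc_se + .data$se_twins1) ~ "twins1_higher",
          .data$diff < -2 * (.data$mc_se + .data$se_twins1) ~ "twins1_lower",
          TRUE ~ "comparable"
        )
      ) |>
      dplyr::select(
        "a_G", "a_GxE", "noise_law", "scale", "model",
        "rate_twins1", rate_other = "discovery_rate", "diff", "flag"
      )
  } else {
    tibble::tibble()
  }

  monotonicity <- table |>
    dplyr::group_by(.data$model, .data$a_G, .data$noise_law, .data$scale) |>
    dplyr::arrange(.data$a_GxE, .by_group = TRUE) |>
    dplyr::summarise(
      monotone_in_a_gxe = all(diff(.data$discovery_rate) >= -2 * utils::head(.data$mc_se, -1) - 2 * utils::tail(.data$mc_se, -1)),
      .groups = "drop"
    )

  list(
    calibration = calibration,
    power_comparisons = power_comparisons,
    monotonicity = monotonicity
  )
}

#' Bartlett's equal-variance test as a singleton-design comparator
#'
#' Bartlett's k-sample test of equal phenotype variance across genotype
#' groups. Included as the comparator used by earlier singleton vQTL work;
#' it is well calibrated for normal phenotypes but anti-conservative under
#' skewed noise, which is the motivation for the twin-difference models.
#'
#' @param phenotype Numeric phenotype vector.
#' @param genotype Dosage vector (grouped by rounded hard call).
#' @return One-row tibble: `model = "Bartlett"`, `statistic`, `p`, `n`.
#' @export
bartlett_comparator <- function(phenotype, genotype) {
  grp <- factor(round(genotype))
  counts <- table(grp)
  if (length(counts) < 2 || any(counts < 2)) {
    rlang::abort("Bartlett's test needs >= 2 genotype groups with >= 2 observations")
  }
  if (all(tapply(phenotype, grp, stats::var) == 0)) {
    return(tibble::tibble(
      model = "Bartlett", slope = NA_real_, se = NA_real_,
      statistic = 0, p = 1, n = length(phenotype), n_dropped = 0L
    ))
  }
  bt <- stats::bartlett.test(phenotype, grp)
  tibble::tibble(
    model = "Bartlett", slope = NA_real_, se = NA_real_,
    statistic = unname(bt$statistic), p = bt$p.value,
    n = length(phenotype), n_dropped = 0L
  )
}
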