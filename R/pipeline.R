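#' End-to-end variance-QTL mapping pipeline for a twin cohort
#'
#' Runs the full discovery chain on a [twin_cohort()]: SNP and probe QC,
#' optional exclusion of CpGs in supplied regions (e.g. imprinted regions),
#' per-CpG residualization of the intra-pair absolute difference and the
#' within-pair mean, permutation-calibrated cis scans for variance
#' (residual difference) and mean (residual mean) signals, joint LD
#' clumping with removal of variance signals dominated by a stronger mean
#' signal in the same clump, and — for SNPs called as both — the conditional
#' refit that removes the fitted mean genotype effect before retesting.
#'
#' @param cohort A [twin_cohort()].
#' @param covariate_set Residualization covariate layout
#'   (`"simulation"`/`"cohort"`).
#' @param window_bp Cis window (default 1e6).
#' @param n_perm Permutations per CpG (default 10000).
#' @param q_threshold Storey q cutoff (default 0.05).
#' @param exclude Optional region tibble (`chrom`, `start`, `end`) of CpGs
#'   to remove before mapping.
#' @param clump_window_bp,clump_r2 Spurious-filter clumping parameters.
#' @param conditional Run the mean-effect conditional refit on dual signals.
#' @param seed Master seed.
#' @return List with `snp_qc`, `probe_qc`, `vme` and `me` ([cis_scan()]
#'   tables), `vme_calls` (filtered variance signals), `spurious_audit`,
#'   and `conditional` (refit results for dual SNPs).
#' @export
map_vmeqtl <- function(cohort, covariate_set = "simulation",
                       window_bp = 1e6, n_perm = 10000, q_threshold = 0.05,
                       exclude = NULL, clump_window_bp = 5e5, clump_r2 = 0.2,
                       conditional = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  snp_qc <- filter_snps(cohort$genotype)
  probe_qc <- filter_probes(cohort$methylation)
  geno <- cohort$genotype[snp_qc$keep, , drop = FALSE]
  cpg_pos <- cohort$cpg_pos[cohort$cpg_pos$id %in% probe_qc$cpg[probe_qc$keep], ]
  if (!is.null(exclude)) cpg_pos <- exclude_regions(cpg_pos, exclude)
  snp_pos <- cohort$snp_pos[cohort$snp_pos$id %in% rownames(geno), ]
  cpgs <- cpg_pos$id

  pair_ids <- colnames(geno)
  res_abs <- matrix(NA_real_, length(cpgs), length(pair_ids),
    dimnames = list(cpgs, pair_ids)
  )
  res_mean <- res_abs
  for (cpg in cpgs) {
    res_abs[cpg, ] <- residualize_difference(cohort, cpg, covariate_set)[pair_ids]
    res_mean[cpg, ] <- residualize_mean(cohort, cpg, covariate_set)[pair_ids]
  }

  seeds <- derive_seeds(seed, 3)
  vme <- cis_scan(res_abs, geno, snp_pos, cpg_pos,
    window_bp = window_bp, n_perm = n_perm,
    q_threshold = q_threshold, seed = seeds[1]
  )
  me <- cis_scan(res_mean, geno, snp_pos, cpg_pos,
    window_bp = window_bp, n_perm = n_perm,
    q_threshold = q_threshold, seed = seeds[2]
  )

  sig_tbl <- function(scan) {
    scan |>
      dplyr::filter(.data$significant) |>
      dplyr::transmute(
        cpg = .data$cpg, snp = .data$lead_snp,
        p = .data$p_beta, type = "cis"
      )
  }
  vme_sig <- sig_tbl(vme)
  me_sig <- sig_tbl(me)
  filt <- remove_spurious_vmeqtls(vme_sig, me_sig, geno, snp_pos,
    window_bp = clump_window_bp, r2_threshold = clump_r2
  )
  vme_calls <- filt$kept

  cond <- tibble::tibble()
  if (conditional && nrow(vme_calls) > 0) {
    dual <- dplyr::inner_join(vme_calls, me_sig,
      by = c("cpg", "snp"), suffix = c("_vme", "_me")
    )
    if (nrow(dual) > 0) {
      cond <- purrr::map_dfr(seq_len(nrow(dual)), function(i) {
        r <- refit_conditional_on_meqtl(
          cohort, dual$cpg[i], dual$snp[i],
          covariate_set = covariate_set
        )
        thr <- vme$nominal_threshold[vme$cpg == dual$cpg[i]]
        thr <- if (length(thr) == 1 && !is.na(thr)) thr else 0.05
        tibble::tibble(
          cpg = dual$cpg[i], snp = dual$snp[i],
          conditional_p = r$p, threshold = thr,
          kept = r$p < thr
        )
      })
      dropped <- cond$cpg[!cond$kept]
      vme_calls <- vme_calls[!(vme_calls$cpg %in% dropped), ]
    }
  }

  list(
    snp_qc = snp_qc, probe_qc = probe_qc, vme = vme, me = me,
    vme_calls = vme_calls, spurious_audit = filt$audit, conditional = cond
  )
}

#' Write QTL result tables as tidy TSV files
#'
#' @param results Named list of data frames (e.g. the output of
#'   [map_vmeqtl()], matrices excluded).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results_tsv <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]]) && nrow(results[[nm]]) > 0) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      readr::write_tsv(results[[nm]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
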