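# Trans QTL mapping with permutation-count FDR, LD clumping, and the
# spurious variance-signal filter.

#' Trans QTL scan with permutation-count FDR threshold
#'
#' Tests every SNP-CpG pair outside the cis window (different chromosome,
#' or same chromosome and farther than `window_bp`). The significance
#' threshold is calibrated by `n_perm` whole-scan permutations of the pair
#' labels of the residual matrix:
#' `FDR(t) = (N(p_perm < t) / N(p_real < t)) / n_perm`,
#' and the reported threshold is the largest real p-value `t` with
#' `FDR(t) <= fdr`. Significant pairs are LD-clumped per CpG (window and
#' r-squared as in [ld_clump()]) so only index SNPs remain.
#'
#' @param residuals Residual matrix, CpGs x pairs.
#' @param genotypes Dosage matrix, SNPs x pairs.
#' @param snp_pos,cpg_pos Position tibbles (`id`, `chrom`, `pos`).
#' @param window_bp Cis exclusion window (default 1e6).
#' @param n_perm Number of permutations (default 20).
#' @param fdr FDR level (default 0.05).
#' @param clump_window_bp,clump_r2 Clumping parameters (defaults 5e5, 0.2).
#' @param seed Seed for the permutations.
#' @return List with `threshold` (NA when no threshold reaches the FDR
#'   level), `fdr_at_threshold`, and `pairs`: a tibble of significant
#'   (clumped) CpG-SNP pairs with `cpg`, `snp`, `slope`, `p`, `is_index`.
#' @export
trans_scan <- function(residuals, genotypes, snp_pos, cpg_pos,
                       window_bp = 1e6, n_perm = 20, fdr = 0.05,
                       clump_window_bp = 5e5, clump_r2 = 0.2, seed = 1L) {
  stopifnot(ncol(residuals) == ncol(genotypes))
  n <- ncol(residuals)
  snp_pos <- tibble::as_tibble(snp_pos)[match(rownames(genotypes), tibble::as_tibble(snp_pos)$id), ]
  cpg_pos <- tibble::as_tibble(cpg_pos)[match(rownames(residuals), tibble::as_tibble(cpg_pos)$id), ]

  # trans mask: TRUE where the pair is tested (outside the cis window)
  same_chrom <- outer(cpg_pos$chrom, snp_pos$chrom, "==")
  dist <- abs(outer(cpg_pos$pos, snp_pos$pos, "-"))
  trans_mask <- !(same_chrom & dist <= window_bp)
  if (!any(trans_mask)) {
    return(list(threshold = NA_real_, fdr_at_threshold = NA_real_, pairs = tibble::tibble()))
  }

  R_std <- standardize_rows(residuals)
  G_std <- standardize_rows(genotypes)
  ok_cpg <- !is.na(R_std[, 1])
  ok_snp <- !is.na(G_std[, 1])
  R_std <- R_std[ok_cpg, , drop = FALSE]
  G_std <- G_std[ok_snp, , drop = FALSE]
  trans_mask <- trans_mask[ok_cpg, ok_snp, drop = FALSE]

  cor_p <- function(Rm) {
    r <- (Rm %*% t(G_std)) / (n - 1)
    cor_pval(r, n)
  }
  p_real <- cor_p(R_std)
  real_pool <- sort(p_real[trans_mask])

  set.seed(seed)
  perm_pool <- numeric(0)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    perm_pool <- c(perm_pool, cor_p(R_std[, idx, drop = FALSE])[trans_mask])
  }
  perm_pool <- sort(perm_pool)

  # streaming threshold search over the sorted real p-values:
  # FDR(t) = (#perm < t / #real < t) / n_perm, t from the real pool
  n_perm_below <- findInterval(real_pool, perm_pool, left.open = TRUE)
  # strict "<": at t = real_pool[i], reals strictly below t are those before
  # the first occurrence of that value in the sorted pool
  n_real_strict <- match(real_pool, real_pool) - 1
  fdr_t <- ifelse(n_real_strict > 0,
    (n_perm_below / n_real_strict) / n_perm, NA_real_
  )
  ok <- which(!is.na(fdr_t) & fdr_t <= fdr)
  if (length(ok) == 0) {
    return(list(threshold = NA_real_, fdr_at_threshold = NA_real_, pairs = tibble::tibble()))
  }
  t_idx <- max(ok)
  threshold <- real_pool[t_idx]
  counts <- list(
    n_real_below = n_real_strict[t_idx],
    n_perm_below = n_perm_below[t_idx]
  )

  sig <- which(p_real < threshold & trans_mask, arr.ind = TRUE)
  if (nrow(sig) == 0) {
    return(c(list(
      threshold = threshold, fdr_at_threshold = fdr_t[t_idx],
      pairs = tibble::tibble()
    ), counts))
  }
  pairs <- tibble::tibble(
    cpg = rownames(R_std)[sig[, 1]],
    snp = rownames(G_std)[sig[, 2]],
    p = p_real[sig]
  )
  # per-CpG clumping: keep one index SNP per LD clump
  pairs <- pairs |>
    dplyr::group_by(.data$cpg) |>
    dplyr::group_modify(function(df, key) {
      cl <- ld_clump(df$snp, df$p, genotypes, snp_pos,
        window_bp = clump_window_bp, r2_threshold = clump_r2
      )
      dplyr::mutate(df, is_index = .data$snp %in% cl$clumps$index_snp)
    }) |>
    dplyr::ungroup()
  c(list(
    threshold = threshold, fdr_at_threshold = fdr_t[t_idx],
    pairs = dplyr::filter(pairs, .data$is_index)
  ), counts)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unassigned SNP with the smallest p-value as an index
#' SNP and assigns every unassigned SNP within `window_bp` of it (same
#' chromosome) whose squared Pearson dosage correlation with the index is at
#' least `r2_threshold` to its clump. Ties in p are broken by
#' (chromosome, position, id) lexical order, so the result is deterministic.
#'
#' @param snps SNP identifiers to clump.
#' @param p Their p-values (same order).
#' @param genotypes Dosage matrix (SNPs x samples) holding at least `snps`.
#' @param positions Position tibble (`id`, `chrom`, `pos`).
#' @param window_bp Clump window (default 5e5).
#' @param r2_threshold Minimum squared correlation with the index
#'   (default 0.2).
#' @return List of class `clump_set`: `clumps` tibble (`index_snp`,
#'   `member_snp`, `r2`, `p_member`) where each index also appears as its
#'   own member with `r2 = 1`, and the parameters used.
#' @export
ld_clump <- function(snps, p, genotypes, positions,
                     window_bp = 5e5, r2_threshold = 0.2) {
  stopifnot(length(snps) == length(p))
  positions <- tibble::as_tibble(positions)
  info <- positions[match(snps, positions$id), ]
  if (anyNA(info$pos)) rlang::abort("positions missing for some SNPs")
  ord <- order(p, info$chrom, info$pos, snps)
  G <- genotypes[snps, , drop = FALSE]
  assigned <- rep(FALSE, length(snps))
  rows <- list()
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    cand <- which(!assigned &
      info$chrom == info$chrom[i] &
      abs(info$pos - info$pos[i]) <= window_bp)
    r2 <- if (length(cand) > 0) {
      as.numeric(stats::cor(G[i, ], t(G[cand, , drop = FALSE])))^2
    } else {
      numeric(0)
    }
    members <- cand[!is.na(r2) & r2 >= r2_threshold]
    assigned[members] <- TRUE
    rows[[length(rows) + 1]] <- tibble::tibble(
      index_snp = snps[i],
      member_snp = c(snps[i], snps[members]),
      r2 = c(1, r2[!is.na(r2) & r2 >= r2_threshold]),
      p_member = c(p[i], p[members])
    )
  }
  structure(
    list(
      clumps = dplyr::bind_rows(rows),
      window_bp = window_bp, r2_threshold = r2_threshold
    ),
    class = "clump_set"
  )
}

#' Remove variance-QTL signals explained by stronger mean-QTL signals in LD
#'
#' A SNP in partial LD with a mean-level QTL can show up as a spurious
#' variance QTL. For each CpG carrying both signal types, all of its
#' variance- and mean-QTL SNPs are jointly LD-clumped; when a variance-QTL
#' SNP falls in the same clump as a mean-QTL SNP and the mean signal is the
#' strongest in the clump, the variance-QTL SNP is discarded. Clumping is
#' run separately for each combination of signal localisation present in
#' the inputs (cis/cis, trans/trans, cis/trans, trans/cis) when a `type`
#' column is supplied.
#'
#' @param vme Tibble of variance-QTL signals: `cpg`, `snp`, `p`, optional
#'   `type` (`"cis"`/`"trans"`).
#' @param me Tibble of mean-QTL signals, same columns.
#' @param genotypes Dosage matrix covering all SNPs involved.
#' @param positions SNP position tibble.
#' @param window_bp,r2_threshold Clumping parameters (defaults 5e5, 0.2).
#' @return List: `kept` (filtered `vme` tibble) and `audit` (one row per
#'   discarded signal with the dominating mean-QTL SNP).
#' @export
remove_spurious_vmeqtls <- function(vme, me, genotypes, positions,
                                    window_bp = 5e5, r2_threshold = 0.2) {
  vme <- tibble::as_tibble(vme)
  me <- tibble::as_tibble(me)
  if (!"type" %in% names(vme)) vme$type <- "cis"
  if (!"type" %in% names(me)) me$type <- "cis"
  drop_keys <- character(0)
  audit <- list()
  combos <- tidyr::expand_grid(vtype = unique(vme$type), mtype = unique(me$type))
  for (k in seq_len(nrow(combos))) {
    v_sub <- dplyr::filter(vme, .data$type == combos$vtype[k])
    m_sub <- dplyr::filter(me, .data$type == combos$mtype[k])
    shared <- intersect(v_sub$cpg, m_sub$cpg)
    for (cpg in shared) {
      v_c <- dplyr::filter(v_sub, .data$cpg == !!cpg)
      m_c <- dplyr::filter(m_sub, .data$cpg == !!cpg)
      all_snps <- c(v_c$snp, m_c$snp)
      all_p <- c(v_c$p, m_c$p)
      kind <- rep(c("vme", "me"), c(nrow(v_c), nrow(m_c)))
      cl <- ld_clump(all_snps, all_p, genotypes, positions,
        window_bp = window_bp, r2_threshold = r2_threshold
      )
      members <- cl$clumps
      members$kind <- kind[match(members$member_snp, all_snps)]
      # strongest signal in each clump is its index (smallest p by greedy
      # construction); discard vme members of clumps led by a mean signal
      for (ix in unique(members$index_snp)) {
        grp <- members[members$index_snp == ix, ]
        lead_kind <- grp$kind[grp$member_snp == ix][1]
        if (lead_kind == "me" && any(grp$kind == "vme")) {
          bad <- grp$member_snp[grp$kind == "vme"]
          drop_keys <- c(drop_keys, paste(cpg, bad, combos$vtype[k]))
          audit[[length(audit) + 1]] <- tibble::tibble(
            cpg = cpg, discarded_snp = bad,
            vme_type = combos$vtype[k], me_type = combos$mtype[k],
            dominating_meqtl = ix,
            r2_with_index = grp$r2[grp$kind == "vme"]
          )
        }
      }
    }
  }
  kept <- vme[!(paste(vme$cpg, vme$snp, vme$type) %in% drop_keys), ]
  list(kept = kept, audit = dplyr::bind_rows(audit))
}
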