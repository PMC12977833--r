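# SNP / probe QC and the small set-filter utilities.

#' SNP quality-control filter
#'
#' Drops SNPs that (i) fail a 1-df chi-square Hardy-Weinberg
#' goodness-of-fit test at `hwe_p`, (ii) have minor allele frequency below
#' `maf_min`, or (iii) have fewer than `min_group` pairs in any genotype
#' group that is present. Dosages must be hard calls in `{0, 1, 2}`.
#'
#' @param genotypes Dosage matrix, SNPs x pairs.
#' @param hwe_p HWE p-value threshold (default 1e-6).
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param min_group Minimum pairs per present genotype group (default 5).
#' @return Tibble with one row per SNP: `snp`, `keep`, `maf`, `hwe_p`,
#'   `min_group_n`, `reason` (NA when kept; first failed rule otherwise).
#' @export
filter_snps <- function(genotypes, hwe_p = 1e-6, maf_min = 0.05,
                        min_group = 5L) {
  if (!all(genotypes %in% c(0, 1, 2))) {
    rlang::abort("dosages must be hard calls in {0, 1, 2}")
  }
  n <- ncol(genotypes)
  res <- purrr::map_dfr(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    counts <- tabulate(g + 1L, nbins = 3L)
    p_hat <- (2 * counts[3] + counts[2]) / (2 * n)
    maf <- min(p_hat, 1 - p_hat)
    expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    hwe <- if (any(expected == 0)) {
      1 # monomorphic: HWE trivially satisfied; caught by the MAF rule
    } else {
      chisq <- sum((counts - expected)^2 / expected)
      stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    }
    min_grp <- min(counts[counts > 0])
    reason <- dplyr::case_when(
      hwe < hwe_p ~ "hwe",
      maf < maf_min ~ "maf",
      min_grp < min_group ~ "group_size",
      TRUE ~ NA_character_
    )
    tibble::tibble(
      snp = rownames(genotypes)[i], keep = is.na(reason),
      maf = maf, hwe_p = hwe, min_group_n = min_grp, reason = reason
    )
  })
  res
}

#' Probe completeness filter
#'
#' Keeps a methylation probe only if it has no missing values across all
#' samples; imputing missing methylation can distort the distribution and
#' create spurious variance signals.
#'
#' @param methylation Matrix, CpGs x individuals.
#' @return Tibble with `cpg`, `n_missing`, `keep`.
#' @export
filter_probes <- function(methylation) {
  nm <- unname(rowSums(is.na(methylation)))
  tibble::tibble(
    cpg = rownames(methylation) %||% as.character(seq_len(nrow(methylation))),
    n_missing = as.integer(nm),
    keep = nm == 0
  )
}

#' Exclude CpGs falling in genomic regions
#'
#' Removes CpGs whose position falls inside any of the supplied intervals
#' (half-open `[start, end)` convention), e.g. published imprinted regions.
#'
#' @param cpg_pos Position tibble (`id`, `chrom`, `pos`).
#' @param regions Tibble of intervals (`chrom`, `start`, `end`).
#' @return The filtered `cpg_pos` tibble.
#' @export
exclude_regions <- function(cpg_pos, regions) {
  cpg_pos <- tibble::as_tibble(cpg_pos)
  if (is.null(regions) || nrow(regions) == 0) return(cpg_pos)
  inside <- interval_overlap(cpg_pos, regions)
  cpg_pos[!inside, ]
}

#' Cross-platform correlation filter
#'
#' Keeps a probe when the Spearman rank correlation between two platforms'
#' measurements of the same samples reaches `min_rho`; used when the same
#' CpG is profiled on two arrays and low-correlation probes are considered
#' unreliable.
#'
#' @param values_a,values_b Paired per-sample vectors.
#' @param min_rho Minimum Spearman correlation (default 0.2).
#' @return One-row tibble: `rho`, `keep`.
#' @export
correlation_filter <- function(values_a, values_b, min_rho = 0.2) {
  ok <- stats::complete.cases(values_a, values_b)
  if (sum(ok) < 3) rlang::abort("fewer than 3 complete pairs")
  rho <- stats::cor(values_a[ok], values_b[ok], method = "spearman")
  tibble::tibble(rho = rho, keep = rho >= min_rho)
}

#' Bonferroni replication filter
#'
#' Declares a discovery association replicated when its replication-cohort
#' p-value is strictly below `alpha / m`, where `m` is the number of
#' associations tested in the replication cohort.
#'
#' @param replication Tibble with at least a `p` column (one row per tested
#'   association).
#' @param alpha Family-wise level (default 0.05).
#' @return The input tibble with an added logical `replicated` column and
#'   the threshold as attribute `bonferroni_threshold`.
#' @export
bonferroni_replicate <- function(replication, alpha = 0.05) {
  replication <- tibble::as_tibble(replication)
  m <- nrow(replication)
  thr <- if (m > 0) alpha / m else NA_real_
  out <- dplyr::mutate(replication, replicated = .data$p < thr)
  attr(out, "bonferroni_threshold") <- thr
  out
}
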