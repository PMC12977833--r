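# Fisher's-exact annotation enrichment with the minimum-signal rule and
# harmonic-mean odds-ratio aggregation.

#' Fisher's exact enrichment of a query set in an annotation set
#'
#' Builds the 2x2 table of query x annotation membership over the universe
#' and applies a two-tailed Fisher's exact test (summing all tables with
#' probability at most that observed). The reported odds ratio is the
#' conditional maximum-likelihood estimate with its exact 95% CI; a
#' Haldane-corrected sample odds ratio is reported alongside when any cell
#' is zero. Annotations overlapping the query in fewer than `min_signals`
#' elements are skipped, as are degenerate margins (empty or universe-sized
#' sets).
#'
#' @param query,annotation Character vectors of ids, subsets of `universe`.
#' @param universe Character vector of all ids considered.
#' @param annotation_name Label recorded in the output.
#' @param min_signals Minimum query-annotation overlap (default 10).
#' @return One-row tibble: `annotation`, the four table counts
#'   (`n_query_annot`, `n_query_only`, `n_annot_only`, `n_neither`),
#'   `or_estimate`, `or_sample`, `ci_low`, `ci_high`, `p`, `skipped`,
#'   `skip_reason`.
#' @export
fisher_enrichment <- function(query, annotation, universe,
                              annotation_name = "annotation",
                              min_signals = 10L) {
  if (length(universe) == 0) rlang::abort("universe is empty")
  query <- unique(query)
  annotation <- unique(annotation)
  universe <- unique(universe)
  if (!all(query %in% universe)) rlang::abort("query must be a subset of universe")
  if (!all(annotation %in% universe)) rlang::abort("annotation must be a subset of universe")
  a <- length(intersect(query, annotation))
  b <- length(setdiff(query, annotation))
  c_ <- length(setdiff(annotation, query))
  d <- length(universe) - a - b - c_
  base <- tibble::tibble(
    annotation = annotation_name,
    n_query_annot = a, n_query_only = b, n_annot_only = c_, n_neither = d,
    or_estimate = NA_real_, or_sample = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    skipped = TRUE, skip_reason = NA_character_
  )
  if (a < min_signals) {
    base$skip_reason <- "min_signals"
    return(base)
  }
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    base$skip_reason <- "degenerate_margins"
    return(base)
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or_smp <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  dplyr::mutate(base,
    or_estimate = unname(ft$estimate), or_sample = or_smp,
    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
    p = ft$p.value, skipped = FALSE
  )
}

#' Enrichment over a list of annotations with FDR adjustment
#'
#' @param query,universe As in [fisher_enrichment()].
#' @param annotations Named list of id vectors.
#' @param min_signals Minimum overlap per annotation (default 10).
#' @return Tibble with one row per annotation and a BH-adjusted `q` column
#'   (computed over the non-skipped rows).
#' @export
fisher_enrichments <- function(query, annotations, universe,
                               min_signals = 10L) {
  out <- purrr::imap_dfr(
    annotations,
    function(a, nm) fisher_enrichment(query, a, universe, nm, min_signals)
  )
  out$q <- NA_real_
  tested <- !out$skipped
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out
}

#' Point-in-interval membership
#'
#' Tests each (chrom, pos) point for membership in any of the supplied
#' intervals, half-open `[start, end)`: a point at `start` is inside, a
#' point at `end` is outside.
#'
#' @param points Tibble with `chrom`, `pos`.
#' @param regions Tibble with `chrom`, `start`, `end` (`end >= start`).
#' @return Logical vector, one entry per point.
#' @export
interval_overlap <- function(points, regions) {
  points <- tibble::as_tibble(points)
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("chrom", "pos") %in% names(points)))
  if (nrow(regions) == 0) return(rep(FALSE, nrow(points)))
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$end < regions$start)) rlang::abort("malformed interval: end < start")
  vapply(seq_len(nrow(points)), function(i) {
    any(regions$chrom == points$chrom[i] &
      regions$start <= points$pos[i] &
      points$pos[i] < regions$end)
  }, logical(1))
}

#' Harmonic mean of odds ratios
#'
#' `n / sum(1 / OR_i)`, the aggregation used to summarise enrichment across
#' related annotation categories.
#'
#' @param ors Vector of positive odds ratios.
#' @return Single aggregate odds ratio.
#' @export
harmonic_mean_or <- function(ors) {
  if (length(ors) == 0) rlang::abort("no odds ratios supplied")
  if (any(!is.finite(ors) | ors <= 0)) rlang::abort("all odds ratios must be positive and finite")
  length(ors) / sum(1 / ors)
}
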