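#' Twin-pair cohort container
#'
#' Bundles the per-twin covariate table, the per-pair genotype dosage matrix
#' (monozygotic co-twins share germline genotype, so dosages are stored once
#' per pair), the per-individual methylation matrix, and SNP/CpG position
#' tables into a single object consumed by the mapping functions.
#'
#' @param covariates Tibble with one row per twin individual; must contain
#'   `pair_id`, `twin` (1 or 2), `individual_id`, `age`, `sex`, `bmi`,
#'   `smoking`, and optionally `batch` and cell-proportion columns.
#' @param genotype Numeric matrix, SNPs in rows (rownames = SNP ids),
#'   pairs in columns (colnames = pair ids), dosages in `{0, 1, 2}`.
#' @param methylation Numeric matrix, CpGs in rows (rownames = CpG ids),
#'   twin individuals in columns (colnames = `individual_id`).
#' @param snp_pos,cpg_pos Tibbles with columns `id`, `chrom`, `pos`
#'   (1-based).
#' @param scale Methylation scale: `"beta"` (values in `[0, 1]`) or `"M"`
#'   (logit2 transform, unbounded).
#' @param truth Optional tibble recording simulated ground truth.
#' @return An object of class `twin_cohort`.
#' @export
twin_cohort <- function(covariates, genotype, methylation,
                        snp_pos = NULL, cpg_pos = NULL,
                        scale = c("beta", "M"), truth = NULL) {
  scale <- match.arg(scale)
  covariates <- tibble::as_tibble(covariates)
  need <- c("pair_id", "twin", "individual_id", "age", "sex", "bmi", "smoking")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0) {
    rlang::abort(paste0("covariates lacks column(s): ", paste(miss, collapse = ", ")))
  }
  genotype <- as.matrix(genotype)
  methylation <- as.matrix(methylation)
  pair_ids <- unique(covariates$pair_id)
  if (!identical(sort(colnames(genotype)), sort(as.character(pair_ids)))) {
    rlang::abort("genotype columns must match covariate pair_ids")
  }
  if (!all(colnames(methylation) %in% covariates$individual_id)) {
    rlang::abort("methylation columns must be covariate individual_ids")
  }
  if (!all(genotype %in% c(0, 1, 2))) {
    rlang::abort("genotype dosages must be 0/1/2 (hard calls)")
  }
  if (scale == "beta") {
    rng <- range(methylation, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      rlang::abort("beta-scale methylation must lie in [0, 1]")
    }
  }
  structure(
    list(
      covariates = covariates, genotype = genotype, methylation = methylation,
      snp_pos = if (!is.null(snp_pos)) tibble::as_tibble(snp_pos) else NULL,
      cpg_pos = if (!is.null(cpg_pos)) tibble::as_tibble(cpg_pos) else NULL,
      scale = scale, truth = truth
    ),
    class = "twin_cohort"
  )
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("<twin_cohort> ", ncol(x$genotype), " MZ pairs, ",
    nrow(x$genotype), " SNPs, ", nrow(x$methylation), " CpGs (",
    x$scale, " scale)\n",
    sep = ""
  )
  invisible(x)
}

# Per-pair covariate layout used by the residualization step: wide table with
# one row per pair. Assumes covariates carry twin = 1/2 within each pair.
pair_table <- function(covariates) {
  cov1 <- dplyr::filter(covariates, .data$twin == 1)
  cov2 <- dplyr::filter(covariates, .data$twin == 2)
  cov2 <- cov2[match(cov1$pair_id, cov2$pair_id), ]
  stopifnot(identical(cov1$pair_id, cov2$pair_id))
  tibble::tibble(
    pair_id = cov1$pair_id,
    age = cov1$age,
    sex = cov1$sex,
    bmi_1 = cov1$bmi, bmi_2 = cov2$bmi,
    smoking_1 = cov1$smoking, smoking_2 = cov2$smoking,
    batch_1 = if ("batch" %in% names(cov1)) cov1$batch else NA,
    batch_2 = if ("batch" %in% names(cov1)) cov2$batch else NA
  )
}

#' Write a simulated cohort to plain-text TSV files
#'
#' Writes genotype (SNP x pair), methylation (CpG x individual), covariate,
#' position, and truth tables as tab-separated files, the interchange format
#' consumed by downstream QTL tools.
#'
#' @param cohort A [twin_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat_tbl <- function(m, idcol) {
    tibble::as_tibble(m, rownames = idcol)
  }
  paths <- c(
    genotype = file.path(dir, "genotype.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    covariates = file.path(dir, "covariates.tsv")
  )
  readr::write_tsv(mat_tbl(cohort$genotype, "snp"), paths["genotype"])
  readr::write_tsv(mat_tbl(cohort$methylation, "cpg"), paths["methylation"])
  readr::write_tsv(cohort$covariates, paths["covariates"])
  if (!is.null(cohort$snp_pos)) {
    p <- file.path(dir, "snp_pos.tsv")
    readr::write_tsv(cohort$snp_pos, p)
    paths <- c(paths, snp_pos = p)
  }
  if (!is.null(cohort$cpg_pos)) {
    p <- file.path(dir, "cpg_pos.tsv")
    readr::write_tsv(cohort$cpg_pos, p)
    paths <- c(paths, cpg_pos = p)
  }
  if (!is.null(cohort$truth)) {
    p <- file.path(dir, "truth.tsv")
    readr::write_tsv(cohort$truth, p)
    paths <- c(paths, truth = p)
  }
  invisible(paths)
}
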