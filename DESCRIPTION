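Package: twinvqtl
Title: Variance Methylation QTL Mapping with Monozygotic Twins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of genetic variants associated with the variability
    (rather than the mean) of DNA methylation, using monozygotic twin pairs
    as the unit of analysis. Provides a twin-cohort simulator, six intra-pair
    discordance regression models with a simulation-based evaluation grid,
    permutation-calibrated cis and trans QTL mapping with beta-approximated
    empirical p-values and Storey q-values, LD clumping and removal of
    spurious variance signals tagging mean-level QTLs, two-stage
    gene-environment interaction tests, deviation-regression (DRM) and
    squared-residual (SVLM) variance tests for unrelated samples, and
    Fisher's exact annotation enrichment utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
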