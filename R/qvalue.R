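#' Storey q-values
#'
#' False discovery rate adjusted significance measures with the null
#' proportion `pi0` estimated from the p-value distribution: `pi0(lambda)`
#' is computed on the grid `lambda = 0.05, 0.10, ..., 0.95` and smoothed
#' with a cubic smoothing spline (3 df), taking the fitted value at the
#' largest lambda. With few p-values, or if the estimate degenerates, `pi0`
#' falls back to 1, which reduces to Benjamini-Hochberg.
#'
#' @param p Vector of p-values.
#' @param method `"storey"` or `"bh"` (plain Benjamini-Hochberg).
#' @param lambda Grid of lambda values for pi0 estimation.
#' @return Numeric vector of q-values, same order as `p`, with attribute
#'   `pi0`.
#' @export
storey_qvalue <- function(p, method = c("storey", "bh"),
                          lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) rlang::abort("p-values must be in [0, 1]")
  m <- length(p)
  pi0 <- 1
  if (method == "storey" && m >= 30) {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch(
      {
        sp <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
        stats::predict(sp, x = max(lambda))$y
      },
      error = function(e) 1
    )
    pi0 <- min(max(pi0, 0), 1)
    if (pi0 <= 0) pi0 <- 1
  }
  q <- pi0 * stats::p.adjust(p, method = "BH")
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}
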