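# Internal numerical helpers shared across modules.

#' Min-max scale a numeric vector to [0, 1]
#'
#' Rescales `x` linearly so its minimum maps to 0 and its maximum to 1,
#' preserving the shape of the distribution. A constant vector (zero range)
#' is mapped to all zeros, the defined fallback for degenerate simulation
#' terms.
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]` of the same length.
#' @export
scale01 <- function(x) {
  stopifnot(is.numeric(x))
  if (anyNA(x)) rlang::abort("scale01() does not accept missing values")
  rng <- range(x)
  d <- rng[2] - rng[1]
  if (d <= 0) return(rep(0, length(x)))
  (x - rng[1]) / d
}

# Fast OLS slope test via pivoted QR. X must include an intercept column.
# Returns estimate/se/t/p for the column `coef` of X (1-based, pre-pivot
# indexing), plus residual df. Aliased columns are dropped; if the tested
# column itself is aliased the fit is degenerate and an error is raised.
ols_slope_test <- function(y, X, coef = 2L) {
  qrX <- qr(X)
  r <- qrX$rank
  piv <- qrX$pivot[seq_len(r)]
  if (!(coef %in% piv)) {
    rlang::abort("design is degenerate: tested term is aliased or constant")
  }
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  df <- length(y) - r
  if (df <= 0) rlang::abort("no residual degrees of freedom")
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrX)[seq_len(r), seq_len(r), drop = FALSE]
  Rinv <- backsolve(R, diag(r))
  # var(beta_pivoted) = sigma2 * (R^-1 R^-T); diagonal via row sums of squares
  v <- sigma2 * rowSums(Rinv^2)
  names(v) <- colnames(X)[piv]
  idx <- match(coef, piv)
  est <- beta[coef]
  se <- sqrt(v[idx])
  if (sigma2 <= .Machine$double.eps^0.9) {
    # exactly constant response: no evidence either way, p = 1 convention
    return(list(estimate = unname(est), se = 0, statistic = 0, p = 1, df = df))
  }
  stat <- unname(est / se)
  list(
    estimate = unname(est), se = unname(se), statistic = stat,
    p = 2 * stats::pt(abs(stat), df, lower.tail = FALSE), df = df
  )
}

# Residuals from OLS of y on X (with intercept column supplied by caller);
# aliased columns are dropped by the pivoted QR automatically.
ols_residuals <- function(y, X) {
  qr.resid(qr(X), y)
}

# Deterministic child seeds below 2^31, derived from a master seed. Used so
# that replicates / grid cells / CpGs are independent of execution order.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
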