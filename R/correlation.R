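#' Pearson correlation between two time courses
#'
#' The sample Pearson correlation
#' \deqn{r = \frac{\sum_t (x_{1t}-\bar x_1)(x_{2t}-\bar x_2)}
#'   {\sqrt{\sum_t (x_{1t}-\bar x_1)^2}\sqrt{\sum_t (x_{2t}-\bar x_2)^2}},}
#' the elementary statistic behind every connectivity feature in this
#' package. Errors explicitly on zero-variance input rather than returning
#' NaN.
#'
#' @param x1,x2 numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @examples
#' pearsonCor(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearsonCor <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(x1)) || !all(is.finite(x2)))
    stop("inputs must be finite")
  d1 <- x1 - mean(x1)
  d2 <- x2 - mean(x2)
  s1 <- sum(d1^2)
  s2 <- sum(d2^2)
  if (s1 <= 0 || s2 <= 0)
    stop("degenerate input: zero-variance time course")
  r <- sum(d1 * d2) / sqrt(s1 * s2)
  min(1, max(-1, r))
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with nonnegative observation weights entering the
#' mean, covariance and variances identically. With uniform weights this
#' equals [pearsonCor()]. Used inside each tapered sliding window.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param w nonnegative weights, same length, positive sum.
#' @return correlation in [-1, 1].
#' @export
weightedPearson <- function(x1, x2, w) {
  if (length(x1) != length(x2) || length(x1) != length(w))
    stop("x1, x2 and w must have equal length")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative with positive sum")
  wn <- w / sum(w)
  d1 <- x1 - sum(wn * x1)
  d2 <- x2 - sum(wn * x2)
  v1 <- sum(wn * d1^2)
  v2 <- sum(wn * d2^2)
  if (v1 <= 0 || v2 <= 0)
    stop("degenerate input: zero weighted variance")
  r <- sum(wn * d1 * d2) / sqrt(v1 * v2)
  min(1, max(-1, r))
}

# Weighted correlation matrix of the columns of x (internal, vectorized).
# Returns list(cor=matrix, zeroVar=logical index of degenerate columns).
weightedCorrMatrix <- function(x, w) {
  wn <- w / sum(w)
  mu <- colSums(x * wn)
  xc <- sweep(x, 2L, mu, "-")
  cov <- crossprod(xc * wn, xc)       # sum_t wn_t xc_ti xc_tj
  v <- diag(cov)
  list(cov = cov, var = v)
}

#' Apply Fisher z-transform to correlation values
#'
#' Off-by-default variance-stabilizing transform, atanh(r); provided as an
#' option for downstream feature construction.
#'
#' @param r correlations in (-1, 1); values at +/-1 are clipped inward by
#'   1e-7 before transforming.
#' @return z-values.
#' @export
fisherZ <- function(r) atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, r)))
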