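# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Pearson correlation written directly from the defining sum formula.
oraclePearson <- function(x1, x2) {
  m1 <- sum(x1) / length(x1)
  m2 <- sum(x2) / length(x2)
  num <- 0; d1 <- 0; d2 <- 0
  for (t in seq_along(x1)) {
    num <- num + (x1[t] - m1) * (x2[t] - m2)
    d1 <- d1 + (x1[t] - m1)^2
    d2 <- d2 + (x2[t] - m2)^2
  }
  num / sqrt(d1 * d2)
}

# Weighted Pearson with weights in mean, covariance and variances.
oracleWeightedPearson <- function(x1, x2, w) {
  wn <- w / sum(w)
  m1 <- sum(wn * x1); m2 <- sum(wn * x2)
  num <- sum(wn * (x1 - m1) * (x2 - m2))
  num / sqrt(sum(wn * (x1 - m1)^2) * sum(wn * (x2 - m2)^2))
}

# Full discrete convolution by double loop, then central-L crop and peak
# normalization: the taper construction, from scratch.
oracleTaper <- function(L, sigma) {
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  rect <- rep(1, L)
  nOut <- L + length(kern) - 1L
  full <- numeric(nOut)
  for (i in seq_len(L))
    for (j in seq_along(kern))
      full[i + j - 1L] <- full[i + j - 1L] + rect[i] * kern[j]
  w <- full[(h + 1L):(h + L)]
  w / max(w)
}

# OLS by explicit normal equations.
oracleOLS <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = drop(beta), se = se, df = df)
}

# Benjamini-Hochberg step-up by direct definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, sorted[i] * m / i)
    adj[i] <- val
    prev <- val
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# quick valid correlation matrix from random data
randomCorr <- function(C, n = 200) {
  x <- matrix(rnorm(n * C), n, C)
  stats::cor(x)
}
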