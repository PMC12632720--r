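# Internal helpers: seeded evaluation, PSD repair, file hashing.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed fan-out, kept within 32-bit integer range.
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12721) %% 2147483647)
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping at zero followed by re-normalization to unit diagonal,
#' iterated until the smallest eigenvalue exceeds \code{-tol}. Used by the
#' synthetic generator to repair target matrices after entrywise edits.
#'
#' @param m symmetric numeric matrix.
#' @param tol nonnegative convergence tolerance on the minimum eigenvalue.
#' @param maxIter maximum repair iterations.
#' @return a symmetric positive semi-definite matrix with unit diagonal.
#' @export
projectCorrelation <- function(m, tol = 1e-8, maxIter = 100L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m <- (m + t(m)) / 2
  for (it in seq_len(maxIter)) {
    e <- eigen(m, symmetric = TRUE)
    if (e$values[length(e$values)] >= -tol && max(abs(diag(m) - 1)) <= tol) {
      diag(m) <- 1
      return(m)
    }
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(pmax(diag(m), .Machine$double.eps))
    m <- m / outer(d, d)
    m <- (m + t(m)) / 2
  }
  stop("PSD correlation repair did not converge in ", maxIter,
       " iterations; aging-edge slopes may be too extreme")
}

# md5 of a file (base tools); used for cohort/run manifests.
fileHash <- function(path) unname(tools::md5sum(path))

stopIfNotScalarFinite <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}
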