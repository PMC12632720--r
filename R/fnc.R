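#' Construct a ConnectivityMatrix
#'
#' @param values square symmetric matrix with unit diagonal.
#' @param labels optional component labels.
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(labels)) {
    labels <- rownames(values)
    if (is.null(labels)) labels <- sprintf("IC%02d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(labels, labels)
  new("ConnectivityMatrix", values = values, labels = labels)
}

#' @describeIn connectivityMatrix the C x C correlation matrix.
#' @param m a [ConnectivityMatrix-class].
#' @export
cmValues <- function(m) m@values

#' @describeIn connectivityMatrix component labels.
#' @export
cmLabels <- function(m) m@labels

#' Static functional network connectivity
#'
#' Pearson correlation between every pair of component time courses over the
#' whole scan: a C x C symmetric matrix with unit diagonal. For the
#' 53-component template this yields 53 * 52 / 2 = 1378 unique features via
#' [vectorizeUpper()].
#'
#' @param tc a (cleaned) [Timecourses-class].
#' @return a [ConnectivityMatrix-class]. Apply [fisherZ()] to the vectorized
#'   features if variance-stabilized inputs are wanted downstream.
#' @export
computeSFNC <- function(tc) {
  stopifnot(is(tc, "Timecourses"))
  x <- tc@data
  sds <- apply(x, 2L, stats::sd)
  if (any(sds <= 0))
    stop("degenerate input: zero-variance component(s): ",
         paste(colnames(x)[sds <= 0], collapse = ", "))
  r <- stats::cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r <- (r + t(r)) / 2
  connectivityMatrix(r, colnames(x))
}

#' Dynamic functional network connectivity
#'
#' Slides a tapered window along the scan and computes, at each position,
#' the weighted Pearson correlation between all component pairs (taper
#' weights enter means, covariances and variances identically). Windows are
#' 0-based and half-open: window w covers timepoints [start, start + L).
#' The number of windows is \code{floor((T - L) / stride) + 1}.
#'
#' @param tc a (cleaned) [Timecourses-class].
#' @param window a [TaperedWindow-class], default \code{makeTaper(20, 3)}.
#' @param stride window step in TRs (default 1).
#' @return a [DFNCTensor-class] (W x C x C).
#' @export
computeDFNC <- function(tc, window = makeTaper(20, 3), stride = 1L) {
  stopifnot(is(tc, "Timecourses"), is(window, "TaperedWindow"))
  x <- tc@data
  Tn <- nrow(x); C <- ncol(x); L <- window@L
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1 TR")
  if (Tn < L) stop("scan length T = ", Tn, " is shorter than window L = ", L)
  starts <- seq.int(0L, Tn - L, by = stride)
  W <- length(starts)
  w <- window@weights
  out <- array(NA_real_, dim = c(W, C, C))
  for (k in seq_len(W)) {
    seg <- x[(starts[k] + 1L):(starts[k] + L), , drop = FALSE]
    wc <- weightedCorrMatrix(seg, w)
    if (any(wc$var <= 0))
      stop("degenerate window ", k, " (start ", starts[k],
           "): zero weighted variance in component(s) ",
           paste(colnames(x)[wc$var <= 0], collapse = ", "))
    d <- sqrt(wc$var)
    r <- wc$cov / outer(d, d)
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    out[k, , ] <- (r + t(r)) / 2
  }
  new("DFNCTensor", windows = out, starts = as.integer(starts),
      stride = stride, labels = colnames(x))
}

#' @describeIn computeDFNC the W x C x C array.
#' @param d a [DFNCTensor-class].
#' @export
dfncArray <- function(d) d@windows

#' @describeIn computeDFNC 0-based window start indices.
#' @export
windowStarts <- function(d) d@starts

#' @describeIn computeDFNC number of windows W.
#' @export
nWindows <- function(d) dim(d@windows)[1L]

#' @describeIn computeDFNC one window as a [ConnectivityMatrix-class].
#' @param k window index (1-based).
#' @export
windowMatrix <- function(d, k) connectivityMatrix(d@windows[k, , ], d@labels)

# row-major strict upper triangle of a square matrix
upperRowMajor <- function(m) t(m)[lower.tri(m)]

#' @rdname vectorizeUpper
#' @export
setMethod("vectorizeUpper", "ConnectivityMatrix",
          function(x) upperRowMajor(x@values))

#' @rdname vectorizeUpper
#' @export
setMethod("vectorizeUpper", "matrix", function(x) {
  stopifnot(nrow(x) == ncol(x))
  upperRowMajor(x)
})

#' @rdname vectorizeUpper
#' @export
setMethod("vectorizeUpper", "DFNCTensor", function(x) {
  W <- dim(x@windows)[1L]
  t(vapply(seq_len(W), function(k) upperRowMajor(x@windows[k, , ]),
           numeric(dim(x@windows)[2L] * (dim(x@windows)[2L] - 1L) / 2L)))
})

#' Rebuild a connectivity matrix from its upper-triangle features
#'
#' Inverse of [vectorizeUpper()] for a single matrix: fills the strict upper
#' triangle in row-major order, mirrors it, sets the diagonal to 1.
#'
#' @param v feature vector of length C(C-1)/2.
#' @param labels optional component labels.
#' @return a [ConnectivityMatrix-class].
#' @export
unvectorizeUpper <- function(v, labels = NULL) {
  C <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(C - round(C)) > 1e-9)
    stop("length ", length(v), " is not C(C-1)/2 for integer C")
  C <- as.integer(round(C))
  m <- matrix(0, C, C)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  connectivityMatrix(m, labels)
}

#' @rdname subnetworkSlice
#' @export
setMethod("subnetworkSlice", signature(x = "ConnectivityMatrix"),
  function(x, partition, network) {
    idx <- subnetIndex(x@labels, partition, network)
    connectivityMatrix(x@values[idx, idx, drop = FALSE], x@labels[idx])
  })

#' @rdname subnetworkSlice
#' @export
setMethod("subnetworkSlice", signature(x = "DFNCTensor"),
  function(x, partition, network) {
    idx <- subnetIndex(x@labels, partition, network)
    new("DFNCTensor", windows = x@windows[, idx, idx, drop = FALSE],
        starts = x@starts, stride = x@stride, labels = x@labels[idx])
  })

# map component labels of x onto the partition and return indices in network
subnetIndex <- function(labels, partition, network) {
  plab <- partitionLabels(partition)
  valid <- unique(as.character(plab))
  if (!network %in% valid)
    stop("unknown network '", network, "'; valid labels: ",
         paste(valid, collapse = ", "))
  if (length(labels) != length(plab))
    stop("object has ", length(labels), " components but partition has ",
         length(plab))
  which(as.character(plab) == network)
}

#' Truncate a set of scans to their common minimum length
#'
#' Scan-length harmonization before dFNC: all scans are truncated to the
#' shortest T in the cohort so every subject yields the same number of
#' windows.
#'
#' @param tcs list of [Timecourses-class].
#' @return list of [Timecourses-class], all with equal T.
#' @export
harmonizeScanLength <- function(tcs) {
  stopifnot(length(tcs) > 0L)
  tmin <- min(vapply(tcs, function(t) nrow(t@data), integer(1)))
  lapply(tcs, function(t)
    new("Timecourses", data = t@data[seq_len(tmin), , drop = FALSE],
        TR = t@TR, subjectId = t@subjectId))
}
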