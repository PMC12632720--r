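#' Build a tapered sliding window
#'
#' Convolves a rectangular window of length \code{L} TRs with a discrete
#' Gaussian kernel of standard deviation \code{sigma} TRs (truncated at
#' +/- 4 sigma), keeps the central \code{L} samples and normalizes the peak
#' to 1. With \code{sigma} near zero the taper degenerates to the
#' rectangular window.
#'
#' @param L window length in TRs (>= 3).
#' @param sigma Gaussian kernel SD in TRs (> 0).
#' @return a [TaperedWindow-class].
#' @examples
#' w <- makeTaper(20, 3)
#' plot(taperWeights(w), type = "h")
#' @export
makeTaper <- function(L, sigma) {
  L <- as.integer(L)
  if (L < 3L) stop("window length L must be >= 3 TRs")
  stopIfNotScalarFinite(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be > 0")
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  rect <- rep(1, L)
  # full discrete convolution, length L + 2h
  full <- stats::convolve(rect, rev(kern), type = "open")
  w <- full[(h + 1L):(h + L)]
  w <- w / max(w)
  # enforce exact symmetry against floating-point FFT noise
  w <- (w + rev(w)) / 2
  new("TaperedWindow", L = L, sigma = sigma, weights = w)
}

#' @describeIn makeTaper taper weight vector (length L, peak 1).
#' @param window a [TaperedWindow-class].
#' @export
taperWeights <- function(window) window@weights

#' @describeIn makeTaper window length in TRs.
#' @export
windowLength <- function(window) window@L

#' Sliding-window duration in seconds
#'
#' A window of \code{L} TRs spans \code{L * TR} seconds: 40 s at TR = 2 s,
#' 14.7 s at TR = 0.735 s for the default 20-TR window.
#'
#' @param L window length in TRs (or a [TaperedWindow-class]).
#' @param TR repetition time in seconds.
#' @return duration in seconds.
#' @export
windowDurationSec <- function(L, TR) {
  if (is(L, "TaperedWindow")) L <- L@L
  stopIfNotScalarFinite(TR, "TR")
  as.numeric(L) * TR
}
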