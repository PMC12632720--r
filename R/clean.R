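#' Construct a Timecourses object
#'
#' @param data numeric T x C matrix (rows = timepoints).
#' @param TR repetition time in seconds.
#' @param subjectId scan identifier.
#' @param labels optional component labels (column names).
#' @return a [Timecourses-class].
#' @export
timecourses <- function(data, TR, subjectId = "scan", labels = NULL) {
  data <- as.matrix(data)
  if (!is.null(labels)) colnames(data) <- labels
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("IC%02d", seq_len(ncol(data)))
  new("Timecourses", data = data, TR = TR, subjectId = as.character(subjectId))
}

#' @describeIn timecourses the T x C data matrix.
#' @param tc a [Timecourses-class].
#' @export
tcMatrix <- function(tc) tc@data

#' @describeIn timecourses repetition time in seconds.
#' @export
tcTR <- function(tc) tc@TR

#' @describeIn timecourses scan identifier.
#' @export
tcSubject <- function(tc) tc@subjectId

#' Denoise component time courses
#'
#' Per-column cleaning applied in order: (1) removal of a polynomial trend
#' (orders 1 to \code{detrendOrder}, plus intercept) by least squares;
#' (2) optional regression of nuisance covariates and their temporal
#' derivatives; (3) outlier clipping at \code{madClip} median absolute
#' deviations around the column median; (4) zero-phase Butterworth low-pass
#' filtering below \code{lowpassHz}.
#'
#' Any step can be disabled (\code{detrendOrder = 0}, \code{nuisance = NULL},
#' \code{madClip = Inf}, \code{lowpassHz = NULL}); with everything disabled
#' the input is returned unchanged.
#'
#' @param tc a [Timecourses-class].
#' @param detrendOrder highest polynomial order to remove (0 = off; default 3).
#' @param nuisance optional T x k numeric matrix of nuisance regressors
#'   (e.g. realignment parameters); their first temporal derivatives are
#'   added automatically.
#' @param madClip clip threshold in MADs (default 3.5; \code{Inf} = off).
#' @param lowpassHz low-pass cutoff in Hz (default 0.15; \code{NULL} = off).
#'   Must be below the Nyquist frequency 1/(2 TR).
#' @param filterOrder Butterworth order for the zero-phase filter.
#' @return a cleaned [Timecourses-class].
#' @export
cleanTimecourses <- function(tc, detrendOrder = 3L, nuisance = NULL,
                             madClip = 3.5, lowpassHz = 0.15,
                             filterOrder = 5L) {
  stopifnot(is(tc, "Timecourses"))
  x <- tc@data
  Tn <- nrow(x)
  detrendOrder <- as.integer(detrendOrder)
  if (detrendOrder > 0L) {
    if (Tn <= detrendOrder + 1L)
      stop("need T > detrendOrder + 1 timepoints for detrending")
    basis <- stats::poly(seq_len(Tn), degree = detrendOrder)
    x <- as.matrix(stats::lm.fit(cbind(1, basis), x)$residuals)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != Tn)
      stop("nuisance matrix must have T = ", Tn, " rows")
    deriv <- rbind(0, diff(nuisance))
    x <- as.matrix(stats::lm.fit(cbind(1, nuisance, deriv), x)$residuals)
  }
  if (is.finite(madClip)) {
    x <- apply(x, 2L, function(col) {
      med <- stats::median(col)
      s <- stats::mad(col)
      if (s > 0) {
        lo <- med - madClip * s
        hi <- med + madClip * s
        col <- pmin(hi, pmax(lo, col))
      }
      col
    })
  }
  if (!is.null(lowpassHz)) {
    nyquist <- 1 / (2 * tc@TR)
    if (lowpassHz >= nyquist)
      stop(sprintf(
        "low-pass cutoff %.4g Hz is at or above the Nyquist frequency %.4g Hz (TR = %g s)",
        lowpassHz, nyquist, tc@TR))
    bf <- signal::butter(filterOrder, lowpassHz / nyquist, type = "low")
    x <- apply(x, 2L, function(col) signal::filtfilt(bf, col))
  }
  dimnames(x) <- dimnames(tc@data)
  new("Timecourses", data = x, TR = tc@TR, subjectId = tc@subjectId)
}
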