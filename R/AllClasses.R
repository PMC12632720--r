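#' @import methods
NULL

#' Network partition of independent components
#'
#' Maps each independent component (IC) to exactly one functional network.
#' The shipped template partition assigns 53 ICs to seven networks:
#' subcortical (SCN), auditory (AUD), sensorimotor (SMN), visual (VSN),
#' cognitive control (CCN), default-mode (DMN) and cerebellar (CBN).
#'
#' @slot labels factor; one entry per component, names are component ids,
#'   levels are the network labels.
#' @seealso [networkPartition()], [templatePartition()]
#' @export
setClass("NetworkPartition", representation(labels = "factor"))

setValidity("NetworkPartition", function(object) {
  lab <- object@labels
  if (length(lab) == 0L) return("partition has no components")
  if (anyNA(lab)) return("partition contains NA network labels")
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    return("component ids must be present and unique")
  TRUE
})

#' Component time courses for one scan
#'
#' A T x C matrix of IC time courses (rows = timepoints, columns =
#' components) with the repetition time TR in seconds.
#'
#' @slot data numeric matrix, T x C, all finite.
#' @slot TR numeric(1); repetition time in seconds, > 0.
#' @slot subjectId character(1) scan/subject identifier.
#' @export
setClass("Timecourses",
  representation(data = "matrix", TR = "numeric", subjectId = "character"))

setValidity("Timecourses", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 2L) return("need at least 2 timepoints")
  if (!all(is.finite(d))) return("time courses contain non-finite values")
  if (length(object@TR) != 1L || !is.finite(object@TR) || object@TR <= 0)
    return("TR must be a single positive number (seconds)")
  TRUE
})

#' Tapered sliding window
#'
#' Weights obtained by convolving a rectangular window of length L (in TR
#' units) with a Gaussian kernel, cropped to the central L samples and
#' peak-normalized to 1.
#'
#' @slot L integer(1); window length in TRs, >= 3.
#' @slot sigma numeric(1); Gaussian kernel SD in TRs, > 0.
#' @slot weights numeric(L); nonnegative, symmetric.
#' @seealso [makeTaper()]
#' @export
setClass("TaperedWindow",
  representation(L = "integer", sigma = "numeric", weights = "numeric"))

setValidity("TaperedWindow", function(object) {
  w <- object@weights
  if (object@L < 3L) return("window length L must be >= 3")
  if (length(w) != object@L) return("weights length must equal L")
  if (any(w < 0)) return("weights must be nonnegative")
  if (max(w) <= 0) return("maximum weight must be positive")
  if (max(abs(w - rev(w))) > 1e-8) return("weights must be symmetric")
  TRUE
})

#' Functional network connectivity matrix
#'
#' A C x C correlation matrix between IC time courses: symmetric, unit
#' diagonal, entries in [-1, 1].
#'
#' @slot values numeric C x C matrix.
#' @slot labels character component labels (length C).
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", labels = "character"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("connectivity matrix must be square")
  if (length(object@labels) != nrow(v))
    return("labels length must match matrix dimension")
  if (!all(is.finite(v))) return("connectivity contains non-finite values")
  if (max(abs(v - t(v))) > 1e-8) return("connectivity matrix must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-8) return("diagonal must be 1")
  if (max(abs(v)) > 1 + 1e-8) return("entries must lie in [-1, 1]")
  TRUE
})

#' Dynamic FNC tensor
#'
#' Windowed connectivity: a W x C x C array, one correlation matrix per
#' tapered-window position. Window starts are 0-based and half-open in TR
#' units, i.e. window w covers timepoints [start[w], start[w] + L).
#'
#' @slot windows numeric array W x C x C.
#' @slot starts integer(W) 0-based window start indices.
#' @slot stride integer(1) step between consecutive windows, in TRs.
#' @slot labels character component labels.
#' @export
setClass("DFNCTensor",
  representation(windows = "array", starts = "integer", stride = "integer",
                 labels = "character"))

setValidity("DFNCTensor", function(object) {
  d <- dim(object@windows)
  if (length(d) != 3L) return("windows must be a 3-d array (W x C x C)")
  if (d[2] != d[3]) return("window slices must be square")
  if (length(object@starts) != d[1])
    return("starts length must equal number of windows")
  if (length(object@labels) != d[2])
    return("labels length must match component dimension")
  if (object@stride < 1L) return("stride must be >= 1 TR")
  TRUE
})

#' Synthetic cohort specification
#'
#' All parameters of the synthetic cohort generator. The cohort (phenotypes
#' and time courses) is a pure function of this object, including its seed.
#'
#' Ages are uniform on [ageLow, ageHigh]. A fraction \code{propPatients} of
#' subjects are patients (SZ) carrying an injected brain-age acceleration of
#' \code{delta} years; connectivity on \code{agingEdges} drifts linearly with
#' "effective age" (chronological age + latent brain-age gap), and cognitive
#' scores are negatively coupled to the latent gap through
#' \code{gammaAttention} / \code{gammaMemory}.
#'
#' @slot nSubjects integer(1) cohort size (>= 0).
#' @slot ageLow,ageHigh numeric(1) age range in years, ageLow < ageHigh.
#' @slot propPatients numeric(1) fraction of SZ patients in [0, 1].
#' @slot nSites integer(1) number of acquisition sites.
#' @slot C integer(1) number of components.
#' @slot partition NetworkPartition over the C components.
#' @slot T integer(1) timepoints per scan.
#' @slot TR numeric(1) repetition time, seconds.
#' @slot agingEdges data.frame with columns i, j, base, slope: edges (i < j)
#'   whose correlation is base + slope * (effective age - reference age).
#' @slot refAge numeric(1) reference age at which aging edges sit at base.
#' @slot delta numeric(1) injected brain-age acceleration for patients, years.
#' @slot bagSd numeric(1) SD of the latent brain-age gap around its mean.
#' @slot gammaAttention,gammaMemory numeric(1) cognitive slope per latent year.
#' @slot sigmaCog numeric(1) cognitive noise SD.
#' @slot dynamicDriftSd numeric(1) per-step SD of the slow covariance drift.
#' @slot scansPerSubject integer(1) scans generated per subject (1 or 2).
#' @slot seed integer(1) master seed.
#' @seealso [cohortSpec()]
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", ageLow = "numeric", ageHigh = "numeric",
                 propPatients = "numeric", nSites = "integer", C = "integer",
                 partition = "NetworkPartition", T = "integer", TR = "numeric",
                 agingEdges = "data.frame", refAge = "numeric",
                 delta = "numeric", bagSd = "numeric",
                 gammaAttention = "numeric", gammaMemory = "numeric",
                 sigmaCog = "numeric", dynamicDriftSd = "numeric",
                 scansPerSubject = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
  num <- c(ageLow = object@ageLow, ageHigh = object@ageHigh,
           propPatients = object@propPatients, TR = object@TR,
           refAge = object@refAge, delta = object@delta, bagSd = object@bagSd,
           gammaAttention = object@gammaAttention,
           gammaMemory = object@gammaMemory, sigmaCog = object@sigmaCog,
           dynamicDriftSd = object@dynamicDriftSd)
  bad <- names(num)[!is.finite(num)]
  if (length(bad)) return(paste0("non-finite spec field(s): ",
                                 paste(bad, collapse = ", ")))
  if (object@nSubjects < 0L) return("nSubjects must be >= 0")
  if (object@propPatients < 0 || object@propPatients > 1)
    return("propPatients must lie in [0, 1]")
  if (object@ageLow >= object@ageHigh) return("need ageLow < ageHigh")
  if (object@nSites < 1L) return("need at least one site")
  if (object@C < 2L) return("need at least 2 components")
  if (length(object@partition@labels) != object@C)
    return("partition size must equal C")
  if (object@T < 2L) return("need at least 2 timepoints")
  if (object@TR <= 0) return("TR must be positive")
  ae <- object@agingEdges
  if (nrow(ae)) {
    if (!all(c("i", "j", "base", "slope") %in% names(ae)))
      return("agingEdges needs columns i, j, base, slope")
    if (any(ae$i >= ae$j)) return("agingEdges must have i < j")
    if (any(ae$j > object@C)) return("agingEdges indices must be <= C")
    if (any(ae$i < 1)) return("agingEdges indices must be >= 1")
  }
  if (object@bagSd < 0 || object@sigmaCog < 0 || object@dynamicDriftSd < 0)
    return("SD parameters must be nonnegative")
  if (!object@scansPerSubject %in% c(1L, 2L))
    return("scansPerSubject must be 1 or 2")
  TRUE
})

#' Fitted brain-age regressor
#'
#' A brain-age model trained with grouped K-fold cross-validation: the
#' architecture ("linear_baseline", "bilstm" or "connectome_gcn"), the fitted
#' parameters, the per-fold per-epoch validation MAE and the selected epoch
#' (argmin of mean CV MAE), plus the scope (wide-brain or one network) and
#' modality (sfnc or dfnc) the features came from.
#'
#' @slot architecture character(1).
#' @slot scope character(1): "wide" or a network label.
#' @slot modality character(1): "sfnc" or "dfnc".
#' @slot params list of fitted parameters (opaque).
#' @slot selectedEpoch integer(1).
#' @slot cvReport numeric matrix, folds x epochs, validation MAE.
#' @slot config list echo of the training configuration.
#' @slot featureInfo list describing the expected feature geometry.
#' @export
setClass("BrainAgeModel",
  representation(architecture = "character", scope = "character",
                 modality = "character", params = "list",
                 selectedEpoch = "integer", cvReport = "matrix",
                 config = "list", featureInfo = "list"))

setValidity("BrainAgeModel", function(object) {
  if (!object@architecture %in% c("linear_baseline", "bilstm", "connectome_gcn"))
    return("unknown architecture")
  if (!object@modality %in% c("sfnc", "dfnc")) return("unknown modality")
  rep <- object@cvReport
  if (length(rep)) {
    best <- which.min(colMeans(rep))
    if (object@selectedEpoch != best)
      return("selectedEpoch must minimize mean CV MAE")
  }
  TRUE
})
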