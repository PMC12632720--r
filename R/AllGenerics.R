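#' Vectorize the strict upper triangle of a connectivity object
#'
#' Returns the strict upper triangle in row-major order: (1,2), (1,3), ...,
#' (1,C), (2,3), ..., (C-1,C). Length C(C-1)/2 (1378 for C = 53). For a
#' [DFNCTensor-class] each window is vectorized, giving a W x C(C-1)/2 matrix.
#' The inverse is [unvectorizeUpper()].
#'
#' @param x a [ConnectivityMatrix-class], [DFNCTensor-class] or square matrix.
#' @return numeric vector (or W-row matrix for tensors).
#' @export
setGeneric("vectorizeUpper", function(x) standardGeneric("vectorizeUpper"))

#' Restrict a connectivity object to one functional network
#'
#' Keeps only rows/columns of components belonging to \code{network},
#' preserving component order; applied per window for tensors.
#'
#' @param x a [ConnectivityMatrix-class] or [DFNCTensor-class].
#' @param partition a [NetworkPartition-class].
#' @param network a network label present in the partition.
#' @return object of the same class, restricted.
#' @export
setGeneric("subnetworkSlice",
  function(x, partition, network) standardGeneric("subnetworkSlice"))

#' Predict brain age from connectivity features
#'
#' Applies a fitted [BrainAgeModel-class] to new features. Inference is
#' deterministic (dropout disabled); repeated calls return identical values.
#'
#' @param model a [BrainAgeModel-class].
#' @param features features with the geometry the model was trained on (see
#'   [trainBrainAgeCV()]).
#' @return numeric vector of predicted ages (years), one per scan.
#' @export
setGeneric("predictAge", function(model, features) standardGeneric("predictAge"))
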