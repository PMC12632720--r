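setMethod("show", "NetworkPartition", function(object) {
  tab <- table(object@labels)
  cat("NetworkPartition:", length(object@labels), "components,",
      length(tab), "networks\n")
  cat(paste(sprintf("%s(%d)", names(tab), as.integer(tab)),
            collapse = " "), "\n")
})

setMethod("show", "Timecourses", function(object) {
  cat(sprintf("Timecourses '%s': T = %d, C = %d, TR = %g s (%.1f s scan)\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@TR, nrow(object@data) * object@TR))
})

setMethod("show", "TaperedWindow", function(object) {
  cat(sprintf("TaperedWindow: L = %d TR, sigma = %g TR, peak = %g\n",
              object@L, object@sigma, max(object@weights)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  C <- nrow(object@values)
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("ConnectivityMatrix: %d x %d (%d unique features)\n",
              C, C, (C * (C - 1L)) %/% 2L))
  if (length(off))
    cat(sprintf("  off-diagonal range [%.3f, %.3f]\n", min(off), max(off)))
})

setMethod("show", "DFNCTensor", function(object) {
  d <- dim(object@windows)
  cat(sprintf("DFNCTensor: W = %d windows of %d x %d (stride %d TR)\n",
              d[1L], d[2L], d[3L], object@stride))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: n = %d (%.0f%% SZ), ages %g-%g, C = %d, T = %d, TR = %g s\n",
    object@nSubjects, 100 * object@propPatients, object@ageLow,
    object@ageHigh, object@C, object@T, object@TR))
  cat(sprintf(
    "  %d aging edges, delta = %g y, drift SD = %g, seed = %d\n",
    nrow(object@agingEdges), object@delta, object@dynamicDriftSd,
    object@seed))
})

setMethod("show", "BrainAgeModel", function(object) {
  cat(sprintf("BrainAgeModel: %s [%s/%s]\n", object@architecture,
              object@modality, object@scope))
  if (length(object@cvReport))
    cat(sprintf("  %d-fold CV, selected epoch %d (mean CV MAE %.3f y)\n",
                nrow(object@cvReport), object@selectedEpoch,
                min(colMeans(object@cvReport))))
})
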