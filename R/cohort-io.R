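#' Write a cohort to disk
#'
#' Writes the phenotype table as TSV, each scan as a plain-text matrix
#' (TSV with a header comment carrying TR and subject id), and a JSON
#' manifest listing every file with its md5 hash, the generator seed and an
#' echo of the cohort spec.
#'
#' @param phenotypes phenotype data.frame (one row per subject).
#' @param timecourses named list of [Timecourses-class] (one per scan).
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param spec optional [CohortSpec-class] echoed into the manifest.
#' @return (invisibly) the manifest as a list.
#' @export
writeCohort <- function(phenotypes, timecourses, dir, overwrite = FALSE,
                        spec = NULL) {
  if (dir.exists(dir) && length(dir(dir, all.files = TRUE, no.. = TRUE)) &&
      !overwrite)
    stop("directory '", dir, "' exists and is not empty; use overwrite = TRUE")
  nScansPer <- length(timecourses) / max(1L, nrow(phenotypes))
  if (nrow(phenotypes) > 0 &&
      length(timecourses) %% nrow(phenotypes) != 0)
    stop("number of scans (", length(timecourses),
         ") is not a multiple of the number of subjects (",
         nrow(phenotypes), ")")
  dir.create(file.path(dir, "tc"), recursive = TRUE, showWarnings = FALSE)
  phenoPath <- file.path(dir, "phenotypes.tsv")
  utils::write.table(phenotypes, phenoPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  scanEntries <- lapply(names(timecourses), function(sid) {
    tc <- timecourses[[sid]]
    p <- file.path(dir, "tc", paste0(sid, ".tsv"))
    con <- file(p, "w")
    writeLines(sprintf("# TR: %.10g", tc@TR), con)
    writeLines(sprintf("# subject: %s", tc@subjectId), con)
    utils::write.table(tc@data, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    list(scan = sid, file = file.path("tc", paste0(sid, ".tsv")),
         TR = tc@TR, md5 = fileHash(p))
  })
  manifest <- list(
    format = "fncBrainAge cohort v1",
    phenotypes = list(file = "phenotypes.tsv", md5 = fileHash(phenoPath)),
    scans = scanEntries,
    seed = if (!is.null(spec)) spec@seed else NA_integer_,
    spec = if (!is.null(spec)) specAsList(spec) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort from disk
#'
#' Inverse of [writeCohort()]. The latent ground-truth column
#' \code{true_bag} is dropped unless \code{includeLatent = TRUE}, so
#' analysis code cannot accidentally condition on it.
#'
#' @param dir cohort directory containing manifest.json.
#' @param includeLatent keep latent simulation-only columns (tests only).
#' @param verifyHashes check file md5 sums against the manifest.
#' @return list(phenotypes, timecourses, manifest).
#' @export
readCohort <- function(dir, includeLatent = FALSE, verifyHashes = TRUE) {
  mPath <- file.path(dir, "manifest.json")
  if (!file.exists(mPath)) stop("no manifest.json under '", dir, "'")
  manifest <- jsonlite::read_json(mPath, simplifyVector = FALSE)
  phenoPath <- file.path(dir, manifest$phenotypes$file)
  if (verifyHashes && !identical(unname(fileHash(phenoPath)),
                                 manifest$phenotypes$md5))
    stop("phenotype file hash mismatch; cohort may be corrupted")
  ph <- utils::read.delim(phenoPath, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  if (!includeLatent) ph$true_bag <- NULL
  tcs <- list()
  for (entry in manifest$scans) {
    p <- file.path(dir, entry$file)
    if (verifyHashes && !identical(unname(fileHash(p)), entry$md5))
      stop("scan file hash mismatch for '", entry$scan, "'")
    tcs[[entry$scan]] <- readTimecoursesTSV(p)
  }
  list(phenotypes = ph, timecourses = tcs, manifest = manifest)
}

#' Read a plain-text time-course matrix
#'
#' Reads a TSV matrix of component time courses. Leading comment lines of
#' the form \code{# TR: <sec>} and \code{# subject: <id>} set the metadata;
#' otherwise \code{TR} and \code{subjectId} must be supplied.
#'
#' @param path file path.
#' @param TR fallback repetition time (seconds).
#' @param subjectId fallback scan id.
#' @return a [Timecourses-class].
#' @export
readTimecoursesTSV <- function(path, TR = NULL, subjectId = NULL) {
  head <- readLines(path, n = 5L)
  trLine <- grep("^# TR:", head, value = TRUE)
  idLine <- grep("^# subject:", head, value = TRUE)
  if (length(trLine)) TR <- as.numeric(sub("^# TR:\\s*", "", trLine[1]))
  if (length(idLine)) subjectId <- sub("^# subject:\\s*", "", idLine[1])
  if (is.null(TR)) stop("TR not found in file header and not supplied")
  if (is.null(subjectId)) subjectId <- basename(path)
  d <- utils::read.delim(path, comment.char = "#")
  timecourses(as.matrix(d), TR = TR, subjectId = subjectId)
}

# spec -> plain list for JSON echo
specAsList <- function(spec) {
  list(nSubjects = spec@nSubjects, ageLow = spec@ageLow,
       ageHigh = spec@ageHigh, propPatients = spec@propPatients,
       nSites = spec@nSites, C = spec@C,
       partition = as.list(stats::setNames(
         as.character(partitionLabels(spec@partition)),
         names(partitionLabels(spec@partition)))),
       T = spec@T, TR = spec@TR,
       agingEdges = spec@agingEdges, refAge = spec@refAge,
       delta = spec@delta, bagSd = spec@bagSd,
       gammaAttention = spec@gammaAttention, gammaMemory = spec@gammaMemory,
       sigmaCog = spec@sigmaCog, dynamicDriftSd = spec@dynamicDriftSd,
       scansPerSubject = spec@scansPerSubject, seed = spec@seed)
}
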