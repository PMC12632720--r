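#' Assemble a pipeline run configuration
#'
#' Canonicalizes all stage parameters into a plain, YAML-serializable list.
#' \code{parseRunConfig(serializeRunConfig(cfg))} returns an identical
#' object.
#'
#' @param cohortDir directory holding (or receiving) the cohort.
#' @param outDir output directory for features, models, BAGs and results.
#' @param seed master seed; every stage derives its sub-seeds from it.
#' @param cohort named list of [cohortSpec()] arguments (scalar fields only;
#'   the aging-edge set is derived from \code{C} via [defaultAgingEdges()]).
#' @param fnc list: windowLength (TRs), sigma (TRs), stride (TRs),
#'   detrendOrder, madClip, lowpassHz (NULL disables).
#' @param model list of [modelConfig()] arguments applied to every
#'   (modality, scope) regressor.
#' @param association list: outcomes, minAge.
#' @return nested list of class "runConfig".
#' @export
runConfig <- function(cohortDir, outDir, seed = 1L,
                      cohort = list(), fnc = list(), model = list(),
                      association = list()) {
  cohortDefaults <- list(nSubjects = 200L, ageLow = 40, ageHigh = 80,
                         propPatients = 0.5, nSites = 3L, C = 20L,
                         T = 150L, TR = 2, delta = 5, bagSd = 4,
                         gammaAttention = -0.5, gammaMemory = -0.5,
                         sigmaCog = 3, dynamicDriftSd = 0.02,
                         scansPerSubject = 1L)
  fncDefaults <- list(windowLength = 20L, sigma = 3, stride = 1L,
                      detrendOrder = 0L, madClip = Inf, lowpassHz = NULL)
  modelDefaults <- list(architecture = "linear_baseline", profile = "desk")
  assocDefaults <- list(outcomes = c("attention", "working_memory"),
                        minAge = 38)
  merge1 <- function(def, usr) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    def[names(usr)] <- usr
    def
  }
  cfg <- list(cohortDir = as.character(cohortDir),
              outDir = as.character(outDir),
              seed = as.integer(seed),
              cohort = merge1(cohortDefaults, cohort),
              fnc = merge1(fncDefaults, fnc),
              model = merge1(modelDefaults, model),
              association = merge1(assocDefaults, association))
  intFields <- c("nSubjects", "nSites", "C", "T", "scansPerSubject")
  cfg$cohort[intFields] <- lapply(cfg$cohort[intFields], as.integer)
  cfg$fnc$windowLength <- as.integer(cfg$fnc$windowLength)
  cfg$fnc$stride <- as.integer(cfg$fnc$stride)
  cfg$fnc$detrendOrder <- as.integer(cfg$fnc$detrendOrder)
  structure(cfg, class = "runConfig")
}

#' @describeIn runConfig write a config to a YAML file.
#' @param cfg a runConfig.
#' @param path YAML file path.
#' @export
serializeRunConfig <- function(cfg, path) {
  x <- unclass(cfg)
  # encode the optional low-pass as a string so NULL survives YAML
  x$fnc$lowpassHz <- if (is.null(x$fnc$lowpassHz)) "off" else x$fnc$lowpassHz
  x$fnc$madClip <- if (is.infinite(x$fnc$madClip)) "off" else x$fnc$madClip
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @describeIn runConfig read a YAML config back into a canonical runConfig.
#' @export
parseRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$fnc$lowpassHz, "off")) x$fnc$lowpassHz <- NULL
  if (identical(x$fnc$madClip, "off")) x$fnc$madClip <- Inf
  runConfig(x$cohortDir, x$outDir, x$seed, x$cohort, x$fnc, x$model,
            x$association)
}

cohortSpecFromConfig <- function(cfg) {
  cc <- cfg$cohort
  do.call(cohortSpec, c(cc, list(seed = cfg$seed)))
}

# scan-level feature extraction shared by the pipeline and the acceptance
# script: returns sfnc matrices, sfnc feature rows and dfnc sequences
extractFeatures <- function(tcs, fncOpts) {
  tcs <- harmonizeScanLength(tcs)
  cleaned <- lapply(tcs, function(tc)
    cleanTimecourses(tc, detrendOrder = fncOpts$detrendOrder,
                     madClip = fncOpts$madClip,
                     lowpassHz = fncOpts$lowpassHz))
  taper <- makeTaper(fncOpts$windowLength, fncOpts$sigma)
  sfnc <- lapply(cleaned, computeSFNC)
  dfnc <- lapply(cleaned, computeDFNC, window = taper,
                 stride = fncOpts$stride)
  list(sfnc = sfnc, dfnc = dfnc)
}

# features for one (modality, scope) from full-cohort sfnc/dfnc objects
scopedFeatures <- function(feats, modality, scope, partition, architecture) {
  if (scope != "wide" &&
      length(networkComponents(partition, scope)) < 2L)
    stop("network '", scope, "' has fewer than 2 components; ",
         "no connectivity features can be formed")
  sliceIt <- function(obj) {
    if (scope == "wide") obj else subnetworkSlice(obj, partition, scope)
  }
  if (modality == "sfnc") {
    mats <- lapply(feats$sfnc, sliceIt)
    if (architecture == "connectome_gcn") return(lapply(mats, cmValues))
    featureRows(mats)
  } else {
    lapply(feats$dfnc, function(d) vectorizeUpper(sliceIt(d)))
  }
}

# stack per-scan feature vectors into an n x p matrix (robust to p = 1)
featureRows <- function(objs) {
  rows <- lapply(objs, vectorizeUpper)
  m <- do.call(rbind, rows)
  rownames(m) <- names(objs)
  m
}

#' Run the full simulate - fnc - train - predict - associate pipeline
#'
#' Executes the five stages in order, writing every intermediate artifact
#' under the configured directories and a JSON run manifest recording the
#' config echo, per-stage outputs with content hashes, consumed seeds and
#' wall-clock times. With \code{resume = TRUE}, stages whose outputs already
#' exist are skipped, so deleting one intermediate file and re-running
#' recomputes only the downstream stages.
#'
#' With the default linear-baseline models the entire run is
#' bit-reproducible from the master seed.
#'
#' @param cfg a [runConfig()].
#' @param resume skip stages whose outputs already exist.
#' @param overwrite allow writing into existing directories.
#' @return (invisibly) the run manifest as a list; the association table is
#'   written to \code{<outDir>/results.tsv}.
#' @export
runPipeline <- function(cfg, resume = FALSE, overwrite = FALSE) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohortSpecFromConfig(cfg)
  partition <- spec@partition
  stages <- list()
  logs <- character()
  sayLog <- function(...) {
    msg <- paste0(...)
    logs <<- c(logs, msg)
    message(msg)
  }
  timeStage <- function(name, outputs, fun) {
    t0 <- proc.time()[["elapsed"]]
    done <- resume && all(file.exists(outputs))
    if (done) {
      sayLog("stage ", name, ": outputs present, skipped (resume)")
    } else {
      fun()
      sayLog("stage ", name, ": done")
    }
    stages[[length(stages) + 1L]] <<- list(
      stage = name, skipped = done, outputs = outputs,
      md5 = lapply(outputs, function(p)
        if (file.exists(p)) unname(fileHash(p)) else NA_character_),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  # 1: simulate -------------------------------------------------------------
  cohortManifest <- file.path(cfg$cohortDir, "manifest.json")
  timeStage("simulate", cohortManifest, function() {
    sayLog("simulate: cohort seed ", spec@seed)
    coh <- generateCohort(spec)
    writeCohort(coh$phenotypes, coh$timecourses, cfg$cohortDir,
                overwrite = overwrite || resume, spec = spec)
  })

  # 2: fnc ------------------------------------------------------------------
  featDir <- file.path(cfg$outDir, "features")
  sfncPath <- file.path(featDir, "sfnc_features.tsv")
  dfncDir <- file.path(featDir, "dfnc")
  timeStage("fnc", sfncPath, function() {
    coh <- readCohort(cfg$cohortDir)
    feats <- extractFeatures(coh$timecourses, cfg$fnc)
    dir.create(dfncDir, recursive = TRUE, showWarnings = FALSE)
    sf <- featureRows(feats$sfnc)
    utils::write.table(sf, sfncPath, sep = "\t", quote = FALSE,
                       col.names = NA)
    for (sid in names(feats$dfnc))
      utils::write.table(vectorizeUpper(feats$dfnc[[sid]]),
                         file.path(dfncDir, paste0(sid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # 3: train ----------------------------------------------------------------
  modelPath <- file.path(cfg$outDir, "models.rds")
  scopes <- c("wide", networkNames(partition))
  timeStage("train", modelPath, function() {
    coh <- readCohort(cfg$cohortDir)
    feats <- loadFeatureStore(sfncPath, dfncDir, spec)
    scanIds <- rownames(feats$sfncFeat)
    subjects <- scanSubject(scanIds)
    ages <- coh$phenotypes$age[match(subjects, coh$phenotypes$id)]
    dx <- coh$phenotypes$dx[match(subjects, coh$phenotypes$id)]
    trainMask <- dx == "HC"  # normative model: healthy scans only
    models <- list()
    predictions <- list()
    for (modality in c("sfnc", "dfnc")) {
      for (scope in scopes) {
        mc <- do.call(modelConfig, c(cfg$model,
                                     list(seed = subSeed(cfg$seed, 50L))))
        sayLog("train: ", modality, "/", scope, " (", mc$architecture,
               ", seed ", mc$seed, ")")
        fx <- storedScopedFeatures(feats, modality, scope, partition,
                                   mc$architecture)
        key <- paste(modality, scope, sep = ".")
        fit <- cohortBrainAge(fx, ages, trainMask, groups = subjects,
                              cfg = mc, scope = scope, modality = modality)
        models[[key]] <- fit$model
        predictions[[key]] <- fit$predictions
      }
    }
    saveRDS(list(models = models, predictions = predictions,
                 scanIds = scanIds), modelPath)
  })

  # 4: predict --------------------------------------------------------------
  bagPath <- file.path(cfg$outDir, "bags.tsv")
  timeStage("predict", bagPath, function() {
    coh <- readCohort(cfg$cohortDir)
    store <- readRDS(modelPath)
    bagTabs <- lapply(names(store$models), function(key) {
      m <- store$models[[key]]
      pred <- store$predictions[[key]]
      subj <- scanSubject(store$scanIds)
      agg <- tapply(pred, subj, mean)
      computeBAG(data.frame(id = names(agg), predicted_age = as.numeric(agg)),
                 coh$phenotypes, modality = m@modality, scope = m@scope)
    })
    bags <- do.call(rbind, bagTabs)
    utils::write.table(bags, bagPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # 5: associate ------------------------------------------------------------
  resultsPath <- file.path(cfg$outDir, "results.tsv")
  timeStage("associate", resultsPath, function() {
    coh <- readCohort(cfg$cohortDir)
    bags <- utils::read.delim(bagPath, stringsAsFactors = FALSE,
                              colClasses = c(id = "character"))
    res <- runSuite(bags, coh$phenotypes,
                    outcomes = cfg$association$outcomes,
                    partition = partition,
                    minAge = cfg$association$minAge)
    utils::write.table(res, resultsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  manifest <- list(config = unclass(cfg), stages = stages, log = logs,
                   versions = list(
                     fncBrainAge = as.character(utils::packageVersion("fncBrainAge")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and run the full association suite in memory
#'
#' Convenience wrapper for simulation studies (power, null calibration):
#' generates a cohort from \code{spec}, extracts sFNC/dFNC features, trains
#' a normative brain-age model per (modality, scope) on healthy scans,
#' derives BAGs for everyone and runs the association suite. No files are
#' written.
#'
#' @param spec a [CohortSpec-class].
#' @param modelCfg a [modelConfig()] applied to every regressor.
#' @param fncOpts list: windowLength, sigma, stride, detrendOrder, madClip,
#'   lowpassHz (defaults: 20-TR taper with sigma 3, stride 1, cleaning off —
#'   synthetic series carry no trends or scanner noise).
#' @param outcomes cognitive outcomes to test.
#' @param minAge strict age filter for the association fits.
#' @param scopes scopes to analyze; default "wide" plus every network.
#' @return list(results = association table, bags, phenotypes, models).
#' @export
runSyntheticSuite <- function(spec, modelCfg = modelConfig(),
                              fncOpts = list(),
                              outcomes = c("attention", "working_memory"),
                              minAge = 38, scopes = NULL) {
  fncDefaults <- list(windowLength = 20L, sigma = 3, stride = 1L,
                      detrendOrder = 0L, madClip = Inf, lowpassHz = NULL)
  fncDefaults[names(fncOpts)] <- fncOpts
  fncOpts <- fncDefaults
  partition <- spec@partition
  if (is.null(scopes)) scopes <- c("wide", networkNames(partition))
  coh <- generateCohort(spec)
  feats <- extractFeatures(coh$timecourses, fncOpts)
  scanIds <- names(coh$timecourses)
  subjects <- scanSubject(scanIds)
  ages <- coh$phenotypes$age[match(subjects, coh$phenotypes$id)]
  dx <- coh$phenotypes$dx[match(subjects, coh$phenotypes$id)]
  trainMask <- dx == "HC"
  models <- list(); bagTabs <- list()
  for (modality in c("sfnc", "dfnc")) {
    for (scope in scopes) {
      fx <- scopedFeatures(feats, modality, scope, partition,
                           modelCfg$architecture)
      key <- paste(modality, scope, sep = ".")
      fit <- cohortBrainAge(fx, ages, trainMask, groups = subjects,
                            cfg = modelCfg, scope = scope,
                            modality = modality)
      models[[key]] <- fit$model
      agg <- tapply(fit$predictions, subjects, mean)
      bagTabs[[key]] <- computeBAG(
        data.frame(id = names(agg), predicted_age = as.numeric(agg)),
        coh$phenotypes, modality = modality, scope = scope)
    }
  }
  bags <- do.call(rbind, bagTabs)
  rownames(bags) <- NULL
  results <- if (identical(sort(scopes),
                           sort(c("wide", networkNames(partition)))))
    runSuite(bags, coh$phenotypes, outcomes, partition, minAge)
  else {
    # custom scope subset: one FDR family per outcome over the tests present
    do.call(rbind, lapply(outcomes, function(oc) {
      sp <- associationSpec(oc, minAge = minAge)
      tab <- do.call(rbind, lapply(
        split(bags, list(bags$modality, bags$scope), drop = TRUE),
        fitAssociation, phenotypes = coh$phenotypes, spec = sp))
      tab <- cbind(family = "custom", tab)
      tab$p_fdr <- bhFDR(tab$p_raw)
      rownames(tab) <- NULL
      tab[, c("outcome", "family", "modality", "scope", "beta", "se",
              "ci_low", "ci_high", "r", "p_raw", "p_fdr", "n")]
    }))
  }
  list(results = results, bags = bags, phenotypes = coh$phenotypes,
       models = models)
}

# read stage-2 artifacts back into memory
loadFeatureStore <- function(sfncPath, dfncDir, spec) {
  sf <- as.matrix(utils::read.delim(sfncPath, row.names = 1L,
                                    check.names = FALSE))
  dfncFiles <- list.files(dfncDir, pattern = "\\.tsv$", full.names = TRUE)
  ids <- sub("\\.tsv$", "", basename(dfncFiles))
  seqs <- stats::setNames(lapply(dfncFiles, function(p)
    as.matrix(utils::read.delim(p, check.names = FALSE))), ids)
  list(sfncFeat = sf, dfncSeqs = seqs[rownames(sf)],
       labels = names(partitionLabels(spec@partition)))
}

# scoped features from the on-disk store (feature vectors, not objects)
storedScopedFeatures <- function(feats, modality, scope, partition,
                                 architecture) {
  C <- length(partitionLabels(partition))
  if (scope == "wide") idx <- seq_len(C)
  else idx <- which(as.character(partitionLabels(partition)) == scope)
  if (length(idx) < 2L && scope != "wide")
    stop("network '", scope, "' has fewer than 2 components; ",
         "no connectivity features can be formed")
  featCols <- pairColumnIndex(C, idx)
  if (modality == "sfnc") {
    if (architecture == "connectome_gcn") {
      return(lapply(seq_len(nrow(feats$sfncFeat)), function(i)
        cmValues(unvectorizeUpper(feats$sfncFeat[i, ]))[idx, idx,
                                                        drop = FALSE]))
    }
    feats$sfncFeat[, featCols, drop = FALSE]
  } else {
    lapply(feats$dfncSeqs, function(s) s[, featCols, drop = FALSE])
  }
}

# columns of the row-major upper-triangle vectorization covering pairs
# within the index set `idx`, ordered as vectorizeUpper of the sliced matrix
pairColumnIndex <- function(C, idx) {
  pos <- matrix(0L, C, C)
  k <- 0L
  for (i in seq_len(C - 1L)) for (j in (i + 1L):C) {
    k <- k + 1L
    pos[i, j] <- k
  }
  cols <- integer(0)
  ni <- length(idx)
  if (ni >= 2L)
    for (a in seq_len(ni - 1L)) for (b in (a + 1L):ni)
      cols <- c(cols, pos[idx[a], idx[b]])
  cols
}
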