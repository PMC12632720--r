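#' Brain-age model training configuration
#'
#' Bundles architecture and optimization settings. Two profiles are
#' provided: \code{"desk"} (hidden 32, 10 epochs) for laptop-scale runs and
#' tests, and \code{"paper"} (hidden 128, 100 epochs), matching the
#' full-scale recipe: three bidirectional recurrent layers, dropout 0.1,
#' Adam on mean absolute error with learning rate 1e-3 and batch size 64,
#' K = 5-fold cross-validation with best-epoch selection.
#'
#' @param architecture one of "linear_baseline", "bilstm", "connectome_gcn".
#' @param profile "desk" or "paper"; sets hiddenUnits/epochs defaults.
#' @param hiddenUnits recurrent (or graph-conv) layer width.
#' @param recurrentLayers number of stacked recurrent layers.
#' @param dropout dropout rate between recurrent layers, in [0, 1).
#' @param bidirectional run the LSTM in both time directions.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param folds K for grouped K-fold cross-validation (>= 2).
#' @param ridgeLambda ridge penalty for the linear baseline.
#' @param seed master seed; fans out to fold assignment, parameter
#'   initialization and batch order.
#' @return a named list of class \code{"brainAgeConfig"}.
#' @export
modelConfig <- function(architecture = c("linear_baseline", "bilstm",
                                         "connectome_gcn"),
                        profile = c("desk", "paper"),
                        hiddenUnits = NULL, recurrentLayers = 3L,
                        dropout = 0.1, bidirectional = TRUE,
                        learningRate = 1e-3, batchSize = 64L,
                        epochs = NULL, folds = 5L, ridgeLambda = 1,
                        seed = 1L) {
  architecture <- match.arg(architecture)
  profile <- match.arg(profile)
  if (is.null(hiddenUnits))
    hiddenUnits <- if (profile == "paper") 128L else 32L
  if (is.null(epochs))
    epochs <- if (profile == "paper") 100L else 10L
  if (folds < 2L) stop("need K >= 2 folds")
  if (epochs < 1L) stop("need epochs >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(architecture = architecture, profile = profile,
                 hiddenUnits = as.integer(hiddenUnits),
                 recurrentLayers = as.integer(recurrentLayers),
                 dropout = dropout, bidirectional = isTRUE(bidirectional),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 ridgeLambda = ridgeLambda, seed = as.integer(seed)),
            class = "brainAgeConfig")
}

# ---- feature preparation ---------------------------------------------------

# Normalize the three accepted feature geometries:
#  linear_baseline: numeric matrix n x p (sFNC feature vectors), or a list of
#    W x p window-feature matrices which are averaged over windows;
#  bilstm: list of W x p matrices (equal W across scans);
#  connectome_gcn: list of C x C matrices / ConnectivityMatrix objects.
prepFeatures <- function(features, architecture) {
  if (architecture == "connectome_gcn") {
    if (is(features, "ConnectivityMatrix")) features <- list(features)
    stopifnot(is.list(features))
    mats <- lapply(features, function(f)
      if (is(f, "ConnectivityMatrix")) cmValues(f) else as.matrix(f))
    C <- nrow(mats[[1L]])
    ok <- vapply(mats, function(m) nrow(m) == C && ncol(m) == C, logical(1))
    if (!all(ok))
      stop("connectome features must all be ", C, " x ", C,
           "; scan ", which(!ok)[1L], " differs")
    checkFinite <- vapply(mats, function(m) all(is.finite(m)), logical(1))
    if (!all(checkFinite))
      stop("non-finite features in scan ", which(!checkFinite)[1L])
    return(list(kind = "mats", x = mats, n = length(mats),
                info = list(C = C)))
  }
  if (architecture == "bilstm") {
    stopifnot(is.list(features))
    seqs <- lapply(features, as.matrix)
    W <- nrow(seqs[[1L]]); p <- ncol(seqs[[1L]])
    ok <- vapply(seqs, function(s) nrow(s) == W && ncol(s) == p, logical(1))
    if (!all(ok))
      stop("window sequences must all be ", W, " x ", p,
           "; scan ", which(!ok)[1L], " differs")
    checkFinite <- vapply(seqs, function(s) all(is.finite(s)), logical(1))
    if (!all(checkFinite))
      stop("non-finite features in scan ", which(!checkFinite)[1L])
    return(list(kind = "seqs", x = seqs, n = length(seqs),
                info = list(W = W, p = p)))
  }
  # linear baseline; window sequences are averaged over windows first
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, function(s)
      colMeans(as.matrix(s))))
  x <- as.matrix(features)
  if (ncol(x) < 1L) stop("feature matrix has no columns")
  if (!all(is.finite(x)))
    stop("non-finite features in scan ",
         which(rowSums(!is.finite(x)) > 0)[1L])
  list(kind = "matrix", x = x, n = nrow(x), info = list(p = ncol(x)))
}

subsetFeatures <- function(fp, idx) {
  if (fp$kind == "matrix") fp$x[idx, , drop = FALSE] else fp$x[idx]
}

# ---- ridge baseline --------------------------------------------------------

ridgeFit <- function(x, y, lambda) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv <= 0] <- 1
  xs <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  ym <- mean(y)
  sv <- svd(xs)
  d <- sv$d
  keep <- d > max(d) * 1e-12
  coefStd <- sv$v[, keep, drop = FALSE] %*%
    ((d[keep] / (d[keep]^2 + lambda)) *
       crossprod(sv$u[, keep, drop = FALSE], y - ym))
  list(mu = mu, sd = sdv, ym = ym, coef = drop(coefStd), lambda = lambda)
}

ridgePredict <- function(fit, x) {
  xs <- sweep(sweep(x, 2L, fit$mu, "-"), 2L, fit$sd, "/")
  drop(xs %*% fit$coef) + fit$ym
}

# ---- shared minibatch trainer ----------------------------------------------

# Train a network (bilstm or gcn) on the given index set, evaluating on a
# validation index set after every epoch. Returns final params, per-epoch
# validation MAE and per-epoch validation predictions.
trainNetwork <- function(fp, ages, trainIdx, valIdx, cfg, seed) {
  nTrain <- length(trainIdx)
  initSeed <- subSeed(seed, 1L)
  headBias <- mean(ages[trainIdx])
  params <- withSeed(initSeed, {
    if (cfg$architecture == "bilstm")
      lstmInitParams(fp$info$p, cfg$hiddenUnits, cfg$recurrentLayers,
                     cfg$bidirectional, headBias = headBias)
    else
      gcnInitParams(fp$info$C, cfg$hiddenUnits, headBias = headBias)
  })
  st <- adamInit(params)
  valMAE <- rep(NA_real_, cfg$epochs)
  valPred <- if (length(valIdx))
    matrix(NA_real_, cfg$epochs, length(valIdx)) else NULL
  xVal <- if (length(valIdx)) subsetFeatures(fp, valIdx) else NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- withSeed(subSeed(seed, 100L + ep), sample.int(nTrain))
    bStarts <- seq.int(1L, nTrain, by = cfg$batchSize)
    for (bi in seq_along(bStarts)) {
      take <- ord[bStarts[bi]:min(nTrain, bStarts[bi] + cfg$batchSize - 1L)]
      idx <- trainIdx[take]
      xb <- subsetFeatures(fp, idx)
      yb <- ages[idx]
      if (cfg$architecture == "bilstm") {
        xs <- batchToTimeList(xb)
        masks <- NULL
        if (cfg$dropout > 0 && cfg$recurrentLayers > 1L) {
          nd <- if (cfg$bidirectional) 2L else 1L
          masks <- withSeed(subSeed(seed, 100000L + ep * 500L + bi), {
            lapply(seq_len(cfg$recurrentLayers - 1L), function(l)
              matrix(stats::rbinom(length(take) * nd * cfg$hiddenUnits, 1L,
                                   1 - cfg$dropout) / (1 - cfg$dropout),
                     length(take), nd * cfg$hiddenUnits))
          })
        }
        fwd <- bilstmForward(xs, params, dropMasks = masks)
        dpred <- sign(fwd$pred - yb) / length(yb)
        grads <- bilstmBackward(dpred, params, fwd$cache)
      } else {
        fwd <- gcnForward(xb, params)
        dpred <- sign(fwd$pred - yb) / length(yb)
        grads <- gcnBackward(dpred, params, fwd$cache)
      }
      upd <- adamUpdate(params, grads, st, cfg$learningRate)
      params <- upd$params
      st <- upd$state
    }
    if (length(valIdx)) {
      pv <- networkPredict(params, xVal, cfg)
      valPred[ep, ] <- pv
      valMAE[ep] <- mean(abs(pv - ages[valIdx]))
    }
  }
  list(params = params, valMAE = valMAE, valPred = valPred)
}

batchToTimeList <- function(seqs) {
  W <- nrow(seqs[[1L]])
  lapply(seq_len(W), function(t)
    t(vapply(seqs, function(s) s[t, ], numeric(ncol(seqs[[1L]])))))
}

networkPredict <- function(params, x, cfg) {
  if (cfg$architecture == "bilstm")
    bilstmForward(batchToTimeList(x), params, dropMasks = NULL,
                  keepCache = FALSE)$pred
  else
    gcnForward(x, params, keepCache = FALSE)$pred
}

# ---- grouped K-fold CV training -------------------------------------------

#' Train a brain-age regressor with grouped K-fold cross-validation
#'
#' Assigns subjects (groups) to K folds so that no subject spans train and
#' validation, trains the configured architecture on each fold's complement
#' while tracking validation MAE per epoch, selects the epoch with minimal
#' mean CV MAE, then refits on all data with that epoch budget. The whole
#' procedure is deterministic given \code{cfg$seed}.
#'
#' Out-of-fold predictions at the selected epoch are retained in the fitted
#' object (\code{oofPredictions()}), giving every scan an honest held-out
#' brain-age estimate.
#'
#' @param features sFNC feature matrix (n x p), list of C x C connectivity
#'   matrices, or list of W x p window-feature sequences, matching the
#'   architecture (see [modelConfig()]).
#' @param ages numeric chronological ages, one per scan.
#' @param groups subject ids, one per scan; scans sharing a group never
#'   straddle a fold boundary. Default: one group per scan.
#' @param cfg a [modelConfig()] list.
#' @param scope "wide" or a network label (metadata echoed on the model).
#' @param modality "sfnc" or "dfnc" (metadata echoed on the model).
#' @return a [BrainAgeModel-class].
#' @export
trainBrainAgeCV <- function(features, ages, groups = NULL, cfg = modelConfig(),
                            scope = "wide", modality = "sfnc") {
  fp <- prepFeatures(features, cfg$architecture)
  n <- fp$n
  if (length(ages) != n) stop("need one age per scan")
  if (!all(is.finite(ages))) stop("ages must be finite")
  if (is.null(groups)) groups <- as.character(seq_len(n))
  groups <- as.character(groups)
  ug <- unique(groups)
  K <- cfg$folds
  if (length(ug) < K)
    stop("fewer distinct groups (", length(ug), ") than folds (", K, ")")
  foldOfGroup <- withSeed(subSeed(cfg$seed, 7L), {
    stats::setNames(rep_len(seq_len(K), length(ug)), sample(ug))
  })
  fold <- unname(foldOfGroup[groups])
  nEpochs <- if (cfg$architecture == "linear_baseline") 1L else cfg$epochs
  cvReport <- matrix(NA_real_, K, nEpochs,
                     dimnames = list(paste0("fold", seq_len(K)),
                                     paste0("epoch", seq_len(nEpochs))))
  oofByEpoch <- matrix(NA_real_, nEpochs, n)
  for (k in seq_len(K)) {
    trainIdx <- which(fold != k)
    valIdx <- which(fold == k)
    if (cfg$architecture == "linear_baseline") {
      fit <- ridgeFit(fp$x[trainIdx, , drop = FALSE], ages[trainIdx],
                      cfg$ridgeLambda)
      pv <- ridgePredict(fit, fp$x[valIdx, , drop = FALSE])
      cvReport[k, 1L] <- mean(abs(pv - ages[valIdx]))
      oofByEpoch[1L, valIdx] <- pv
    } else {
      res <- trainNetwork(fp, ages, trainIdx, valIdx, cfg,
                          seed = subSeed(cfg$seed, 10L + k))
      cvReport[k, ] <- res$valMAE
      oofByEpoch[, valIdx] <- res$valPred
    }
  }
  selectedEpoch <- which.min(colMeans(cvReport))
  # final refit on the union of all folds at the selected epoch budget
  if (cfg$architecture == "linear_baseline") {
    finalFit <- ridgeFit(fp$x, ages, cfg$ridgeLambda)
    params <- list(ridge = finalFit)
  } else {
    cfgSel <- cfg
    cfgSel$epochs <- as.integer(selectedEpoch)
    res <- trainNetwork(fp, ages, seq_len(n), integer(0), cfgSel,
                        seed = subSeed(cfg$seed, 999L))
    params <- list(net = res$params)
  }
  params$oof <- oofByEpoch[selectedEpoch, ]
  params$fold <- fold
  new("BrainAgeModel", architecture = cfg$architecture, scope = scope,
      modality = modality, params = params,
      selectedEpoch = as.integer(selectedEpoch), cvReport = cvReport,
      config = unclass(cfg),
      featureInfo = fp$info)
}

#' @describeIn trainBrainAgeCV out-of-fold (held-out) predictions at the
#'   selected epoch, aligned with the training scans.
#' @param model a [BrainAgeModel-class].
#' @export
oofPredictions <- function(model) model@params$oof

#' @describeIn trainBrainAgeCV CV fold assignment (1..K), one per scan.
#' @export
foldAssignment <- function(model) model@params$fold

#' @describeIn trainBrainAgeCV per-fold, per-epoch validation MAE matrix.
#' @export
cvReport <- function(model) model@cvReport

#' @describeIn trainBrainAgeCV the selected (best mean CV MAE) epoch.
#' @export
selectedEpoch <- function(model) model@selectedEpoch

#' @rdname predictAge
#' @export
setMethod("predictAge", signature(model = "BrainAgeModel"),
  function(model, features) {
    cfg <- model@config
    fp <- prepFeatures(features, model@architecture)
    fi <- model@featureInfo
    if (model@architecture == "linear_baseline") {
      if (fp$info$p != fi$p)
        stop("feature dimension mismatch: model expects p = ", fi$p,
             ", received p = ", fp$info$p)
      return(ridgePredict(model@params$ridge, fp$x))
    }
    if (model@architecture == "bilstm") {
      if (fp$info$p != fi$p)
        stop("feature dimension mismatch: model expects p = ", fi$p,
             ", received p = ", fp$info$p)
      if (fp$info$W != fi$W)
        stop("window-count mismatch: model expects W = ", fi$W,
             ", received W = ", fp$info$W)
    } else if (fp$info$C != fi$C) {
      stop("component mismatch: model expects C = ", fi$C,
           ", received C = ", fp$info$C)
    }
    cfg$architecture <- model@architecture
    networkPredict(model@params$net, fp$x, cfg)
  })

#' Train on healthy scans, predict the whole cohort
#'
#' Mirrors the normative brain-age design: the regressor is fit (with
#' grouped CV) on healthy-control scans only, so patient connectivity never
#' shapes the age norm. Controls receive their out-of-fold predictions;
#' all remaining scans are predicted by the refit model. The result is one
#' honest brain-age estimate per scan.
#'
#' @param features full-cohort features (see [trainBrainAgeCV()]).
#' @param ages chronological ages, one per scan.
#' @param trainMask logical, TRUE for scans in the normative (healthy)
#'   training set.
#' @param groups subject ids per scan.
#' @param cfg a [modelConfig()].
#' @param scope,modality metadata echoed on the model.
#' @return list(model = [BrainAgeModel-class], predictions = numeric per
#'   scan).
#' @export
cohortBrainAge <- function(features, ages, trainMask, groups = NULL,
                           cfg = modelConfig(), scope = "wide",
                           modality = "sfnc") {
  n <- length(ages)
  trainMask <- as.logical(trainMask)
  if (length(trainMask) != n) stop("need one trainMask entry per scan")
  if (!any(trainMask)) stop("empty training set")
  if (is.null(groups)) groups <- as.character(seq_len(n))
  sub <- function(f, idx)
    if (is.matrix(f) || is.data.frame(f)) f[idx, , drop = FALSE] else f[idx]
  trainIdx <- which(trainMask)
  model <- trainBrainAgeCV(sub(features, trainIdx), ages[trainIdx],
                           groups = groups[trainIdx], cfg = cfg,
                           scope = scope, modality = modality)
  pred <- rep(NA_real_, n)
  pred[trainIdx] <- oofPredictions(model)
  if (any(!trainMask))
    pred[which(!trainMask)] <- predictAge(model, sub(features,
                                                     which(!trainMask)))
  list(model = model, predictions = pred)
}

#' Prediction accuracy metrics
#'
#' Mean absolute error (years) and the Pearson correlation between
#' predicted and chronological age.
#'
#' @param pred predicted ages.
#' @param chron chronological ages.
#' @return list(mae, r).
#' @examples
#' evaluatePredictions(c(40, 50), c(42, 46))  # MAE 3
#' @export
evaluatePredictions <- function(pred, chron) {
  if (length(pred) != length(chron)) stop("length mismatch")
  if (!all(is.finite(pred)) || !all(is.finite(chron)))
    stop("inputs must be finite")
  list(mae = mean(abs(pred - chron)), r = pearsonCor(pred, chron))
}
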