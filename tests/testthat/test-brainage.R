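# deterministic feature builder: age plus structured noise
ageFeatures <- function(n, p, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    ages <- runif(n, 40, 80)
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- ages + rnorm(n, 0, noise)
    list(x = x, ages = ages)
  })
}

test_that("model configuration validates its invariants and profiles", {
  desk <- modelConfig("bilstm")
  expect_equal(desk$hiddenUnits, 32L)
  expect_equal(desk$epochs, 10L)
  paper <- modelConfig("bilstm", profile = "paper")
  expect_equal(paper$hiddenUnits, 128L)
  expect_equal(paper$epochs, 100L)
  expect_equal(paper$recurrentLayers, 3L)
  expect_equal(paper$dropout, 0.1)
  expect_equal(paper$learningRate, 1e-3)
  expect_equal(paper$batchSize, 64L)
  expect_equal(paper$folds, 5L)
  expect_error(modelConfig(folds = 1L), "K >= 2")
  expect_error(modelConfig(dropout = 1), "dropout")
  expect_error(modelConfig(epochs = 0L), "epochs")
})

test_that("grouped CV partitions every scan once and never splits a subject", {
  d <- ageFeatures(60, 4)
  groups <- rep(sprintf("G%02d", 1:30), each = 2)
  m <- trainBrainAgeCV(d$x, d$ages, groups = groups,
                       cfg = modelConfig("linear_baseline", seed = 3L))
  fold <- foldAssignment(m)
  expect_length(fold, 60L)
  expect_true(all(fold %in% 1:5))
  expect_true(all(!is.na(oofPredictions(m))))
  # scans of a subject share a fold
  expect_true(all(tapply(fold, groups, function(f) length(unique(f))) == 1))
  expect_error(trainBrainAgeCV(d$x, d$ages, groups = rep("g1", 60),
                               cfg = modelConfig("linear_baseline")),
               "fewer distinct groups")
})

test_that("the linear baseline recovers a noiseless age column almost perfectly", {
  d <- ageFeatures(100, 1)
  m <- trainBrainAgeCV(d$x, d$ages, cfg = modelConfig("linear_baseline"))
  expect_gte(evaluatePredictions(oofPredictions(m), d$ages)$r, 0.999)
})

test_that("baseline predictions equal the closed-form ridge solution", {
  d <- ageFeatures(50, 8, noise = 5, seed = 2)
  lam <- 2.5
  m <- trainBrainAgeCV(d$x, d$ages,
                       cfg = modelConfig("linear_baseline",
                                         ridgeLambda = lam))
  pred <- predictAge(m, d$x)
  # oracle: standardize, solve (X'X + lambda I) b = X'y, add back the mean
  mu <- colMeans(d$x); sdv <- apply(d$x, 2, sd)
  xs <- sweep(sweep(d$x, 2, mu, "-"), 2, sdv, "/")
  b <- solve(crossprod(xs) + diag(lam, 8), crossprod(xs, d$ages - mean(d$ages)))
  oracle <- drop(xs %*% b) + mean(d$ages)
  expect_equal(pred, oracle, tolerance = 1e-8)
})

test_that("predictions are deterministic, batch-invariant and dimension-checked", {
  withr::with_seed(31, {
    seqs <- lapply(1:30, function(i) matrix(rnorm(8 * 3), 8, 3))
    ages <- runif(30, 40, 80)
  })
  cfg <- modelConfig("bilstm", hiddenUnits = 4L, recurrentLayers = 2L,
                     epochs = 2L, batchSize = 8L, seed = 5L)
  m <- trainBrainAgeCV(seqs, ages, cfg = cfg, modality = "dfnc")
  p1 <- predictAge(m, seqs)
  p2 <- predictAge(m, seqs)
  expect_identical(p1, p2)
  expect_equal(predictAge(m, seqs[3]), p1[3], tolerance = 1e-6)
  badW <- list(matrix(rnorm(5 * 3), 5, 3))
  expect_error(predictAge(m, badW), "W = 8")
  badP <- list(matrix(rnorm(8 * 4), 8, 4))
  expect_error(predictAge(m, badP), "p = 3")

  gm <- trainBrainAgeCV(lapply(1:25, function(i) randomCorr(5)),
                        runif(25, 40, 80),
                        cfg = modelConfig("connectome_gcn", epochs = 2L,
                                          seed = 2L))
  expect_error(predictAge(gm, list(randomCorr(6))), "C = 5")
})

test_that("selected epoch is the argmin of mean CV MAE and non-finite features are refused", {
  withr::with_seed(7, {
    seqs <- lapply(1:40, function(i) matrix(rnorm(6 * 2), 6, 2))
    ages <- runif(40, 40, 80)
  })
  cfg <- modelConfig("bilstm", hiddenUnits = 3L, recurrentLayers = 1L,
                     epochs = 4L, batchSize = 16L, seed = 9L)
  m <- trainBrainAgeCV(seqs, ages, cfg = cfg)
  expect_equal(selectedEpoch(m),
               unname(which.min(colMeans(cvReport(m)))))
  seqs[[17]][2, 1] <- NA
  expect_error(trainBrainAgeCV(seqs, ages, cfg = cfg), "scan 17")
})

test_that("a positive-weight linear feature never decreases predicted age", {
  d <- ageFeatures(80, 1)
  m <- trainBrainAgeCV(d$x, d$ages, cfg = modelConfig("linear_baseline"))
  grid <- matrix(seq(30, 90, length.out = 25), ncol = 1)
  pred <- predictAge(m, grid)
  expect_true(all(diff(pred) >= 0))
})

test_that("the sequence model learns an age signal that permuted labels destroy", {
  sp <- cohortSpec(nSubjects = 90L, C = 8L, T = 80L, seed = 33L,
                   agingEdges = defaultAgingEdges(8, frac = 0.5,
                                                  slope = 0.015),
                   propPatients = 0, delta = 0, bagSd = 0.5,
                   dynamicDriftSd = 0)
  coh <- generateCohort(sp)
  seqs <- lapply(coh$timecourses, function(t)
    vectorizeUpper(computeDFNC(t, makeTaper(20, 3), stride = 2L)))
  ages <- coh$phenotypes$age
  cfg <- modelConfig("bilstm", hiddenUnits = 16L, recurrentLayers = 1L,
                     batchSize = 16L, seed = 4L)
  m <- trainBrainAgeCV(seqs, ages, cfg = cfg, modality = "dfnc")
  rTrue <- evaluatePredictions(oofPredictions(m), ages)$r
  permAges <- withr::with_seed(8, sample(ages))
  mPerm <- trainBrainAgeCV(seqs, permAges, cfg = cfg, modality = "dfnc")
  rPerm <- evaluatePredictions(oofPredictions(mPerm), permAges)$r
  expect_gt(rTrue, 0.5)
  expect_gt(rTrue, rPerm)
})

test_that("prediction metrics follow their definitions", {
  expect_equal(evaluatePredictions(c(40, 50), c(42, 46))$mae, 3.0)
  p <- c(41, 52, 63)
  expect_equal(evaluatePredictions(p, p), list(mae = 0, r = 1))
  expect_error(evaluatePredictions(rep(50, 4), c(40, 50, 60, 70)),
               "zero-variance")
})

test_that("normative training uses healthy scans only and predicts everyone", {
  d <- ageFeatures(80, 3, noise = 2, seed = 6)
  hc <- rep(c(TRUE, FALSE), each = 40)
  fit <- cohortBrainAge(d$x, d$ages, hc,
                        cfg = modelConfig("linear_baseline", seed = 2L))
  expect_length(fit$predictions, 80L)
  expect_true(all(is.finite(fit$predictions)))
  # healthy entries carry out-of-fold predictions
  expect_equal(fit$predictions[hc], oofPredictions(fit$model))
  # patient entries come from the refit model
  expect_equal(fit$predictions[!hc],
               predictAge(fit$model, d$x[!hc, , drop = FALSE]))
})
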