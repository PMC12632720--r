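test_that("polynomial detrending annihilates its own model and disabled cleaning is the identity", {
  T <- 120
  t <- seq_len(T)
  cubic <- cbind(2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3,
                 -1 + 0.02 * t^2)
  tc <- timecourses(cubic, TR = 2)
  out <- cleanTimecourses(tc, detrendOrder = 3L, madClip = Inf,
                          lowpassHz = NULL)
  expect_lt(max(abs(tcMatrix(out))), 1e-8)

  noise <- noiseTimecourses(50, 3)
  expect_equal(tcMatrix(cleanTimecourses(noise, detrendOrder = 0L,
                                         madClip = Inf, lowpassHz = NULL)),
               tcMatrix(noise))
})

test_that("nuisance regressors and their derivatives are removed", {
  T <- 200
  withr::with_seed(8, {
    nuis <- matrix(rnorm(T * 2), T, 2)
    signal <- matrix(rnorm(T), T, 1)
  })
  x <- signal + 3 * nuis[, 1, drop = FALSE] - 2 * nuis[, 2, drop = FALSE]
  tc <- timecourses(x, TR = 2)
  out <- cleanTimecourses(tc, detrendOrder = 0L, nuisance = nuis,
                          madClip = Inf, lowpassHz = NULL)
  expect_lt(abs(stats::cor(tcMatrix(out)[, 1], nuis[, 1])), 1e-8)
  expect_lt(abs(stats::cor(tcMatrix(out)[, 1], nuis[, 2])), 1e-8)
})

test_that("low-pass filtering passes slow signals, kills fast ones, and rejects cutoffs at Nyquist", {
  T <- 600
  # 0.05 Hz at TR = 2 s sits well inside the 0.15 Hz passband
  t2 <- (seq_len(T) - 1) * 2
  slow <- timecourses(matrix(sin(2 * pi * 0.05 * t2)), TR = 2)
  outSlow <- cleanTimecourses(slow, detrendOrder = 0L, madClip = Inf)
  expect_gte(sum(tcMatrix(outSlow)^2) / sum(tcMatrix(slow)^2), 0.9)

  # 0.25 Hz at TR = 0.72 s is far above 0.15 Hz
  t07 <- (seq_len(T) - 1) * 0.72
  fast <- timecourses(matrix(sin(2 * pi * 0.25 * t07)), TR = 0.72)
  outFast <- cleanTimecourses(fast, detrendOrder = 0L, madClip = Inf)
  expect_lte(sum(tcMatrix(outFast)^2) / sum(tcMatrix(fast)^2), 0.05)

  # at TR = 4 s the Nyquist frequency 0.125 Hz is below the 0.15 Hz cutoff
  slow4 <- timecourses(matrix(rnorm(100)), TR = 4)
  expect_error(cleanTimecourses(slow4, detrendOrder = 0L, madClip = Inf),
               "0.125")
})

test_that("outlier clipping bounds extreme samples without touching the bulk", {
  x <- c(rnorm(200), 50)
  tc <- timecourses(matrix(x), TR = 2)
  out <- tcMatrix(cleanTimecourses(tc, detrendOrder = 0L, madClip = 3.5,
                                   lowpassHz = NULL))
  expect_lt(max(out), 50)
  expect_lte(max(out), stats::median(x) + 3.5 * stats::mad(x) + 1e-12)
})

test_that("pearson matches its defining formula and handles degenerate input explicitly", {
  x <- c(1.5, 2.2, -0.3, 4.1, 0.0)
  expect_equal(pearsonCor(x, x), 1)
  expect_equal(pearsonCor(x, -2 * x + 7), -1)
  expect_equal(pearsonCor(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- rnorm(20); b <- rnorm(20)
      expect_equal(pearsonCor(a, b), oraclePearson(a, b), tolerance = 1e-12)
      expect_equal(pearsonCor(a, b), stats::cor(a, b), tolerance = 1e-12)
    }
  })
  expect_error(pearsonCor(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(pearsonCor(1:3, 1:4), "equal length")
})

test_that("weighted pearson reduces to pearson under uniform weights and matches its oracle", {
  withr::with_seed(5, {
    a <- rnorm(30); b <- rnorm(30); w <- runif(30)
  })
  expect_equal(weightedPearson(a, b, rep(1, 30)), pearsonCor(a, b),
               tolerance = 1e-12)
  expect_equal(weightedPearson(a, b, w), oracleWeightedPearson(a, b, w),
               tolerance = 1e-12)
  expect_error(weightedPearson(rep(2, 30), b, w), "zero weighted variance")
})

test_that("static FNC equals the brute-force pairwise loop and respects its contract", {
  tc <- noiseTimecourses(80, 6, seed = 3)
  m <- computeSFNC(tc)
  v <- cmValues(m)
  x <- tcMatrix(tc)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(v[i, j], oraclePearson(x[, i], x[, j]), tolerance = 1e-12)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(1, 6))

  # independent noise decorrelates at large T
  big <- noiseTimecourses(10000, 6, seed = 4)
  off <- cmValues(computeSFNC(big))
  expect_lt(max(abs(off[upper.tri(off)])), 0.05)

  bad <- timecourses(cbind(rnorm(50), rep(1, 50)), TR = 2)
  expect_error(computeSFNC(bad), "zero-variance")
})

test_that("correlations are invariant to per-column affine standardization", {
  tc <- noiseTimecourses(150, 5, seed = 6)
  x <- tcMatrix(tc)
  xs <- scale(x) * 3 + 5
  a <- cmValues(computeSFNC(tc))
  b <- cmValues(computeSFNC(timecourses(xs, TR = 2)))
  expect_equal(a, b, tolerance = 1e-10)
  da <- dfncArray(computeDFNC(tc, makeTaper(20, 3)))
  db <- dfncArray(computeDFNC(timecourses(xs, TR = 2), makeTaper(20, 3)))
  expect_equal(da, db, tolerance = 1e-10)
})

test_that("taper construction matches a brute-force convolution and its limit cases", {
  w <- taperWeights(makeTaper(20, 3))
  expect_length(w, 20)
  expect_equal(w, rev(w))
  expect_equal(max(w), 1)
  expect_equal(w, oracleTaper(20, 3), tolerance = 1e-10)
  for (L in c(5, 11, 40)) for (s in c(0.5, 2, 5))
    expect_equal(taperWeights(makeTaper(L, s)), oracleTaper(L, s),
                 tolerance = 1e-10)
  # sigma -> 0 limit: rectangular window
  expect_equal(taperWeights(makeTaper(15, 1e-6)), rep(1, 15),
               tolerance = 1e-10)
  expect_error(makeTaper(2, 3), ">= 3")
  expect_error(makeTaper(20, 0), "sigma")
})

test_that("window durations follow L x TR", {
  expect_equal(windowDurationSec(20, 2), 40)
  expect_equal(windowDurationSec(makeTaper(20, 3), 0.735), 14.7)
})

test_that("dynamic FNC window count, per-window contract and degenerate windows", {
  tc <- noiseTimecourses(490, 4, seed = 9)
  d <- computeDFNC(tc, makeTaper(20, 3), stride = 1L)
  expect_equal(nWindows(d), 471L)
  expect_equal(windowStarts(d)[1], 0L)
  expect_equal(windowStarts(d)[471], 470L)
  arr <- dfncArray(d)
  for (k in c(1, 200, 471)) {
    s <- arr[k, , ]
    expect_equal(s, t(s))
    expect_equal(unname(diag(s)), rep(1, 4))
    expect_lte(max(abs(s)), 1 + 1e-12)
  }
  # stride shortens the window grid per the floor formula
  d3 <- computeDFNC(tc, makeTaper(20, 3), stride = 7L)
  expect_equal(nWindows(d3), floor((490 - 20) / 7) + 1)

  const <- timecourses(cbind(rnorm(40), c(rep(0, 25), rnorm(15))), TR = 2)
  expect_error(computeDFNC(const, makeTaper(20, 3)), "window 1")
})

test_that("a full-length uniform window reproduces static FNC exactly", {
  tc <- noiseTimecourses(60, 5, seed = 10)
  d <- computeDFNC(tc, makeTaper(60, 1e-6), stride = 1L)
  expect_equal(nWindows(d), 1L)
  expect_equal(dfncArray(d)[1, , ], unname(cmValues(computeSFNC(tc))),
               tolerance = 1e-12)
})

test_that("windowed correlations average to the static values for stationary series", {
  tc <- noiseTimecourses(2000, 5, seed = 12)
  d <- computeDFNC(tc, makeTaper(20, 3), stride = 1L)
  avg <- apply(dfncArray(d), c(2, 3), mean)
  expect_lt(max(abs(avg - cmValues(computeSFNC(tc)))), 0.05)
})

test_that("upper-triangle vectorization is row-major with a working inverse", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 12; m[1, 3] <- 13; m[2, 3] <- 23
  m <- m + t(m); diag(m) <- 1
  expect_equal(vectorizeUpper(m), c(12, 13, 23))
  expect_equal(length(vectorizeUpper(randomCorr(2))), 1L)
  cm <- connectivityMatrix(randomCorr(7))
  expect_equal(unname(cmValues(unvectorizeUpper(vectorizeUpper(cm)))),
               unname(cmValues(cm)), tolerance = 1e-12)
  # tensor flavor: one row per window
  tc <- noiseTimecourses(50, 4, seed = 2)
  d <- computeDFNC(tc, makeTaper(20, 3))
  vm <- vectorizeUpper(d)
  expect_equal(dim(vm), c(nWindows(d), 6L))
  expect_equal(vm[3, ], vectorizeUpper(dfncArray(d)[3, , ]))
})

test_that("sub-network slicing partitions the template components exactly", {
  p <- templatePartition()
  expect_length(partitionLabels(p), 53L)
  expect_length(networkNames(p), 7L)
  sizes <- vapply(networkNames(p),
                  function(n) length(networkComponents(p, n)), integer(1))
  expect_equal(sum(sizes), 53L)

  tc <- noiseTimecourses(60, 53, seed = 14)
  m <- computeSFNC(tc)
  seen <- character(0)
  for (net in networkNames(p)) {
    sl <- subnetworkSlice(m, p, net)
    comps <- networkComponents(p, net)
    expect_equal(nrow(cmValues(sl)), length(comps))
    expect_equal(cmValues(sl),
                 cmValues(m)[comps, comps, drop = FALSE])
    seen <- c(seen, comps)
  }
  expect_setequal(seen, names(partitionLabels(p)))
  expect_equal(anyDuplicated(seen), 0L)
  expect_error(subnetworkSlice(m, p, "NOPE"), "SCN")

  d <- computeDFNC(timecourses(tcMatrix(tc)[, 1:53], TR = 2),
                   makeTaper(20, 3), stride = 5L)
  ds <- subnetworkSlice(d, p, "AUD")
  expect_equal(dim(dfncArray(ds))[2:3], c(2L, 2L))
  idx <- which(as.character(partitionLabels(p)) == "AUD")
  expect_equal(dfncArray(ds)[2, , ], dfncArray(d)[2, idx, idx])
})

test_that("scan-length harmonization truncates to the cohort minimum", {
  tcs <- list(noiseTimecourses(80, 3, seed = 1),
              noiseTimecourses(65, 3, seed = 2),
              noiseTimecourses(90, 3, seed = 3))
  h <- harmonizeScanLength(tcs)
  expect_true(all(vapply(h, function(t) nrow(tcMatrix(t)), integer(1)) ==
                    65L))
  expect_equal(tcMatrix(h[[1]]), tcMatrix(tcs[[1]])[1:65, ])
})
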