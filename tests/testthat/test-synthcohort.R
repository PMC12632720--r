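test_that("phenotype generation respects the spec and its seed", {
  sp <- tinySpec(nSubjects = 0L)
  empty <- generatePhenotypes(sp)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("id", "age", "sex", "site", "dx", "attention",
                        "working_memory", "true_bag"))

  sp <- tinySpec(nSubjects = 50L, seed = 9L)
  ph1 <- generatePhenotypes(sp)
  ph2 <- generatePhenotypes(sp)
  expect_identical(ph1, ph2)
  expect_equal(length(unique(ph1$id)), 50L)
  expect_true(all(ph1$age >= sp@ageLow & ph1$age <= sp@ageHigh))
  expect_setequal(unique(ph1$dx), c("HC", "SZ"))
  expect_identical(attr(ph1, "latentColumns"), "true_bag")
})

test_that("uniform ages hit their closed-form mean at large n", {
  sp <- cohortSpec(nSubjects = 2000L, ageLow = 40, ageHigh = 80, seed = 3L)
  ph <- generatePhenotypes(sp)
  se <- (80 - 40) / sqrt(12) / sqrt(2000)
  expect_lt(abs(mean(ph$age) - 60), 3 * se)
})

test_that("invalid cohort specs are rejected with the offending field named", {
  expect_error(tinySpec(delta = NaN), "delta")
  expect_error(tinySpec(sigmaCog = Inf), "sigmaCog")
  expect_error(tinySpec(propPatients = 1.2), "propPatients")
  expect_error(cohortSpec(ageLow = 70, ageHigh = 60), "ageLow < ageHigh")
  bad <- data.frame(i = 5L, j = 3L, base = 0, slope = 0.01)
  expect_error(tinySpec(agingEdges = bad), "i < j")
})

test_that("target connectivity responds linearly to age and stays a valid correlation", {
  flat <- tinySpec(agingEdges = data.frame(i = integer(), j = integer(),
                                           base = numeric(),
                                           slope = numeric()),
                   delta = 0)
  m40 <- cmValues(targetFNC(40, "HC", flat))
  m70sz <- cmValues(targetFNC(70, "SZ", flat))
  expect_equal(m40, m70sz)

  one <- tinySpec(agingEdges = data.frame(i = 2L, j = 5L, base = 0,
                                          slope = 0.005),
                  delta = 0)
  d <- cmValues(targetFNC(60, "HC", one))[2, 5] -
    cmValues(targetFNC(40, "HC", one))[2, 5]
  expect_equal(d, 0.10, tolerance = 1e-12)

  sp <- tinySpec()
  m <- cmValues(targetFNC(55, "SZ", sp))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, sp@C))
  expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_lte(max(abs(m)), 1 + 1e-12)
})

test_that("patient connectivity looks delta years older on aging edges", {
  sp <- tinySpec(delta = 8)
  e <- sp@agingEdges[1, ]
  hc <- cmValues(targetFNC(50, "HC", sp))[e$i, e$j]
  sz <- cmValues(targetFNC(50, "SZ", sp))[e$i, e$j]
  expect_equal(sz - hc, e$slope * 8, tolerance = 1e-10)
})

test_that("PSD repair returns a unit-diagonal PSD matrix and fixes violations", {
  set.seed(4)
  m <- randomCorr(8)
  expect_equal(projectCorrelation(m), m, tolerance = 1e-10)
  bad <- m
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- 0.999
  bad[2, 3] <- bad[3, 2] <- -0.999
  fixed <- projectCorrelation(bad)
  expect_gte(min(eigen(fixed, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_equal(unname(diag(fixed)), rep(1, 8))
})

test_that("simulated time courses have the right shape, seed determinism and target correlation", {
  sp <- tinySpec()
  ph <- generatePhenotypes(sp)
  tc1 <- simulateTimecourses(ph[1, ], sp, seed = 11L)
  tc2 <- simulateTimecourses(ph[1, ], sp, seed = 11L)
  expect_equal(dim(tcMatrix(tc1)), c(sp@T, sp@C))
  expect_identical(tcMatrix(tc1), tcMatrix(tc2))

  # Monte-Carlo convergence: with no drift, sample correlations approach
  # the target at large T
  long <- cohortSpec(nSubjects = 1L, C = 6L, T = 20000L, seed = 2L,
                     agingEdges = data.frame(i = 1L, j = 2L, base = 0.3,
                                             slope = 0),
                     dynamicDriftSd = 0, propPatients = 0)
  phl <- generatePhenotypes(long)
  tcl <- simulateTimecourses(phl[1, ], long, seed = 5L)
  target <- cmValues(targetFNC(phl$age[1], "HC", long,
                               trueBag = phl$true_bag[1]))
  samp <- stats::cor(tcMatrix(tcl))
  expect_lt(max(abs(samp - target)), 0.03)
})

test_that("component/partition mismatch is rejected", {
  sp <- tinySpec()
  ph <- generatePhenotypes(sp)
  broken <- sp
  broken@C <- 99L
  expect_error(simulateTimecourses(ph[1, ], broken, seed = 1L),
               "partition")
})

test_that("cognitive scores recover the injected latent-gap slope", {
  sp <- cohortSpec(nSubjects = 600L, seed = 21L)
  ph <- generatePhenotypes(sp)
  fit <- summary(stats::lm(attention ~ true_bag, data = ph))
  est <- fit$coefficients["true_bag", ]
  expect_lt(abs(est["Estimate"] - sp@gammaAttention), 3 * est["Std. Error"])
})

test_that("repeat scans share phenotypes but differ in noise", {
  sp <- tinySpec(nSubjects = 4L, T = 40L, scansPerSubject = 2L)
  coh <- generateCohort(sp)
  expect_length(coh$timecourses, 8L)
  expect_setequal(unique(sub("_r[0-9]+$", "", names(coh$timecourses))),
                  coh$phenotypes$id)
  a <- tcMatrix(coh$timecourses[["S0001_r1"]])
  b <- tcMatrix(coh$timecourses[["S0001_r2"]])
  expect_false(identical(a, b))
  expect_equal(dim(a), dim(b))
})

test_that("cohort write/read round-trips with integrity checking", {
  sp <- tinySpec(nSubjects = 10L, T = 30L)
  coh <- generateCohort(sp)
  d <- withr::local_tempdir()
  man <- writeCohort(coh$phenotypes, coh$timecourses, d, overwrite = TRUE,
                     spec = sp)
  expect_length(man$scans, 10L)

  back <- readCohort(d, includeLatent = TRUE)
  expect_equal(back$phenotypes$true_bag, coh$phenotypes$true_bag,
               tolerance = 1e-12)
  expect_equal(back$phenotypes$id, coh$phenotypes$id)
  for (sid in names(coh$timecourses))
    expect_equal(unname(tcMatrix(back$timecourses[[sid]])),
                 unname(tcMatrix(coh$timecourses[[sid]])),
                 tolerance = 1e-9)
  expect_equal(tcTR(back$timecourses[[1]]), sp@TR)

  # loader hides the latent ground truth by default
  expect_false("true_bag" %in% names(readCohort(d)$phenotypes))

  # refusal to clobber
  expect_error(writeCohort(coh$phenotypes, coh$timecourses, d),
               "overwrite")

  # corrupting an array breaks its manifest hash
  f <- file.path(d, "tc", paste0(coh$phenotypes$id[1], ".tsv"))
  txt <- readLines(f)
  txt[4] <- paste0(txt[4], "1")
  writeLines(txt, f)
  expect_error(readCohort(d), "hash mismatch")
})
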