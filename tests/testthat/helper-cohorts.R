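# Shared cohort fixtures, built in code at test time.

# small, quick cohort: 7 networks all populated needs C >= 14
tinySpec <- function(nSubjects = 30L, C = 14L, T = 60L, seed = 1L, ...)
  cohortSpec(nSubjects = nSubjects, C = C, T = T, seed = seed, ...)

# strong, clean age signal: healthy-only cohort with no latent-gap noise to
# speak of and no covariance drift
strongSignalSpec <- function(nSubjects = 160L, C = 12L, T = 120L, seed = 7L)
  cohortSpec(nSubjects = nSubjects, C = C, T = T, seed = seed,
             agingEdges = defaultAgingEdges(C, frac = 0.4, slope = 0.015),
             propPatients = 0, delta = 0, bagSd = 0.5, dynamicDriftSd = 0)

# phenotype table with controllable structure for association tests
assocPhenotypes <- function(n, seed = 1, nSites = 2) {
  withr::with_seed(seed, {
    data.frame(id = sprintf("S%04d", seq_len(n)),
               age = runif(n, 40, 80),
               sex = sample(c("F", "M"), n, TRUE),
               site = sample(sprintf("site%02d", seq_len(nSites)), n, TRUE),
               dx = sample(c("HC", "SZ"), n, TRUE),
               stringsAsFactors = FALSE)
  })
}

# deterministic Timecourses from white noise
noiseTimecourses <- function(T, C, TR = 2, seed = 1) {
  withr::with_seed(seed, timecourses(matrix(rnorm(T * C), T, C), TR = TR))
}
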