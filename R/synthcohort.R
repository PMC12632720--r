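#' Default set of age-sensitive connectivity edges
#'
#' Deterministically selects a fixed fraction of the C(C-1)/2 component
#' pairs (evenly spaced through the row-major pair ordering) and assigns
#' them alternating-sign per-year slopes around a zero baseline. These edges
#' are the generative "aging signature" a brain-age model must learn.
#'
#' @param C component count.
#' @param frac fraction of pairs that age (default 0.15).
#' @param slope absolute per-year slope in correlation units (default 0.004).
#' @param base baseline correlation at the reference age (default 0).
#' @return data.frame with columns i, j, base, slope.
#' @export
defaultAgingEdges <- function(C, frac = 0.2, slope = 0.012, base = 0) {
  pairs <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  # order row-major: by i then j
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  nP <- nrow(pairs)
  k <- max(1L, round(frac * nP))
  sel <- unique(round(seq(1L, nP, length.out = k)))
  data.frame(i = pairs[sel, 1L], j = pairs[sel, 2L], base = base,
             slope = slope * rep_len(c(1, -1), length(sel)))
}

#' Build a synthetic cohort specification
#'
#' Assembles and validates a [CohortSpec-class]. Defaults describe a
#' mid-to-late adulthood cohort scanned at TR = 2 s with a modest aging
#' signature; see the package vignette for the rationale behind each value.
#'
#' @param nSubjects number of subjects.
#' @param ageLow,ageHigh uniform age range in years.
#' @param propPatients fraction of SZ patients.
#' @param nSites number of acquisition sites.
#' @param C number of components.
#' @param partition a [NetworkPartition-class] over C components; by default
#'   the 7 template networks are recycled across the C components.
#' @param T timepoints per scan.
#' @param TR repetition time, seconds.
#' @param agingEdges data.frame(i, j, base, slope); default
#'   [defaultAgingEdges()].
#' @param refAge reference age (years) at which aging edges sit at their
#'   baseline; default the midpoint of the age range.
#' @param delta injected brain-age acceleration for patients, years.
#' @param bagSd SD of the latent brain-age gap, years.
#' @param gammaAttention,gammaMemory cognitive slope per latent year.
#' @param sigmaCog cognitive noise SD.
#' @param dynamicDriftSd per-step SD of the slow covariance drift.
#' @param scansPerSubject 1 or 2 scans per subject (2 exercises grouped CV).
#' @param seed master seed; the whole cohort is a pure function of the spec.
#' @return a [CohortSpec-class].
#' @examples
#' sp <- cohortSpec(nSubjects = 10, C = 8, T = 60, seed = 7)
#' ph <- generatePhenotypes(sp)
#' head(ph)
#' @export
cohortSpec <- function(nSubjects = 200L, ageLow = 40, ageHigh = 80,
                       propPatients = 0.5, nSites = 3L, C = 20L,
                       partition = NULL, T = 150L, TR = 2,
                       agingEdges = defaultAgingEdges(C),
                       refAge = (ageLow + ageHigh) / 2,
                       delta = 5, bagSd = 4,
                       gammaAttention = -0.5, gammaMemory = -0.5,
                       sigmaCog = 3, dynamicDriftSd = 0.02,
                       scansPerSubject = 1L, seed = 1L) {
  if (is.null(partition)) {
    nets <- c("SCN", "AUD", "SMN", "VSN", "CCN", "DMN", "CBN")
    partition <- networkPartition(rep_len(nets, C))
  }
  # Class named exactly: a plain positional call would let `C` partially
  # match new()'s Class argument
  new(Class = "CohortSpec", nSubjects = as.integer(nSubjects), ageLow = ageLow,
      ageHigh = ageHigh, propPatients = propPatients,
      nSites = as.integer(nSites), C = as.integer(C), partition = partition,
      T = as.integer(T), TR = TR, agingEdges = agingEdges, refAge = refAge,
      delta = delta, bagSd = bagSd, gammaAttention = gammaAttention,
      gammaMemory = gammaMemory, sigmaCog = sigmaCog,
      dynamicDriftSd = dynamicDriftSd,
      scansPerSubject = as.integer(scansPerSubject), seed = as.integer(seed))
}

#' Generate the phenotype table of a synthetic cohort
#'
#' Draws ages uniformly on [ageLow, ageHigh]; assigns sex, site and
#' diagnosis by categorical draws; gives patients a latent brain-age gap
#' centered at \code{delta} years (controls at 0, both with SD
#' \code{bagSd}); and generates cognitive scores as
#' \code{baseline + gamma * true_bag + Normal(0, sigmaCog)}.
#' Fully reproducible from the spec's seed.
#'
#' The latent column \code{true_bag} is flagged via the \code{"latentColumns"}
#' attribute and dropped by the cohort loader unless explicitly requested;
#' the analysis pipeline never reads it.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with columns id, age, sex, site, dx, attention,
#'   working_memory, true_bag.
#' @export
generatePhenotypes <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- spec@nSubjects
  ph <- withSeed(subSeed(spec@seed, 1L), {
    if (n == 0L) {
      data.frame(id = character(), age = numeric(), sex = character(),
                 site = character(), dx = character(), attention = numeric(),
                 working_memory = numeric(), true_bag = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      id <- sprintf("S%04d", seq_len(n))
      age <- stats::runif(n, spec@ageLow, spec@ageHigh)
      sex <- sample(c("F", "M"), n, replace = TRUE)
      site <- sample(sprintf("site%02d", seq_len(spec@nSites)), n,
                     replace = TRUE)
      dx <- sample(c("HC", "SZ"), n, replace = TRUE,
                   prob = c(1 - spec@propPatients, spec@propPatients))
      trueBag <- ifelse(dx == "SZ", spec@delta, 0) +
        stats::rnorm(n, 0, spec@bagSd)
      attention <- 50 + spec@gammaAttention * trueBag +
        stats::rnorm(n, 0, spec@sigmaCog)
      memory <- 50 + spec@gammaMemory * trueBag +
        stats::rnorm(n, 0, spec@sigmaCog)
      data.frame(id = id, age = age, sex = sex, site = site, dx = dx,
                 attention = attention, working_memory = memory,
                 true_bag = trueBag, stringsAsFactors = FALSE)
    }
  })
  attr(ph, "latentColumns") <- "true_bag"
  ph
}

#' Age- and diagnosis-dependent target connectivity
#'
#' The ground-truth correlation matrix a subject's time courses are sampled
#' from: identity plus the aging edges at
#' \code{base + slope * (effectiveAge - refAge)}, where the effective age is
#' chronological age plus the latent brain-age gap (by default \code{delta}
#' for patients, 0 for controls). Entries are clipped to [-0.99, 0.99] and
#' the matrix is projected to the nearest valid correlation matrix
#' (eigenvalue clipping at 0, re-normalized to unit diagonal).
#'
#' @param age chronological age in years (finite).
#' @param diagnosis "HC" or "SZ".
#' @param spec a [CohortSpec-class].
#' @param trueBag optional subject-specific latent gap overriding the
#'   diagnosis-mean shift.
#' @return a [ConnectivityMatrix-class] (C x C).
#' @export
targetFNC <- function(age, diagnosis = c("HC", "SZ"), spec, trueBag = NULL) {
  diagnosis <- match.arg(diagnosis)
  stopIfNotScalarFinite(age, "age")
  if (is.null(trueBag)) trueBag <- if (diagnosis == "SZ") spec@delta else 0
  effAge <- age + trueBag
  C <- spec@C
  m <- diag(C)
  ae <- spec@agingEdges
  if (nrow(ae)) {
    val <- ae$base + ae$slope * (effAge - spec@refAge)
    val <- pmin(0.99, pmax(-0.99, val))
    for (k in seq_len(nrow(ae))) {
      m[ae$i[k], ae$j[k]] <- val[k]
      m[ae$j[k], ae$i[k]] <- val[k]
    }
  }
  m <- projectCorrelation(m)
  connectivityMatrix(m, names(partitionLabels(spec@partition)))
}

#' Simulate component time courses for one subject
#'
#' Samples a T x C matrix from a zero-mean Gaussian process whose
#' instantaneous covariance is the subject's target correlation plus a
#' slowly drifting perturbation. The drift acts multiplicatively on the
#' Cholesky factor of the target: with \eqn{L = chol(R)^\top} the step-t
#' factor is \eqn{A_t = L (I + E_t)}, where \eqn{E_t} is an entrywise
#' Gaussian random walk with per-step SD \code{dynamicDriftSd}. The
#' instantaneous covariance \eqn{A_t A_t^\top = R + L(E_t + E_t^\top +
#' E_t E_t^\top)L^\top} is positive semi-definite by construction and is
#' renormalized to unit variances at every step, so each instantaneous
#' matrix is a valid correlation matrix. With \code{dynamicDriftSd = 0} the
#' process is stationary with exactly the target covariance. Deterministic
#' given \code{seed}.
#'
#' @param row one row of the phenotype table (needs age, dx, true_bag, id).
#' @param spec a [CohortSpec-class].
#' @param seed integer seed for this scan.
#' @param scanId identifier recorded on the result (default the row id).
#' @return a [Timecourses-class] (T x C).
#' @export
simulateTimecourses <- function(row, spec, seed, scanId = row$id) {
  stopifnot(is(spec, "CohortSpec"))
  if (spec@C != length(partitionLabels(spec@partition)))
    stop("component count C = ", spec@C, " does not match partition size ",
         length(partitionLabels(spec@partition)))
  trueBag <- if ("true_bag" %in% names(row)) row$true_bag else NULL
  target <- cmValues(targetFNC(row$age, row$dx, spec, trueBag = trueBag))
  Tn <- spec@T; C <- spec@C
  x <- withSeed(seed, {
    if (spec@dynamicDriftSd == 0) {
      z <- matrix(stats::rnorm(Tn * C), Tn, C)
      z %*% chol(target + diag(1e-10, C))
    } else {
      L <- t(chol(target + diag(1e-10, C)))
      E <- matrix(0, C, C)
      out <- matrix(NA_real_, Tn, C)
      for (t in seq_len(Tn)) {
        E <- E + matrix(stats::rnorm(C * C, 0, spec@dynamicDriftSd), C, C)
        A <- L %*% (diag(C) + E)
        # renormalize rows so each component has unit instantaneous variance
        A <- A / sqrt(rowSums(A^2))
        out[t, ] <- A %*% stats::rnorm(C)
      }
      out
    }
  })
  colnames(x) <- names(partitionLabels(spec@partition))
  new("Timecourses", data = x, TR = spec@TR, subjectId = as.character(scanId))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: phenotypes plus one (or two) simulated scans per
#' subject, each with its own deterministic sub-seed.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements \code{phenotypes} (data.frame) and
#'   \code{timecourses} (named list of [Timecourses-class]; names are scan
#'   ids \code{<id>} or \code{<id>_r1} / \code{<id>_r2}).
#' @export
generateCohort <- function(spec) {
  ph <- generatePhenotypes(spec)
  tcs <- list()
  if (nrow(ph)) {
    k <- 0L
    for (i in seq_len(nrow(ph))) {
      for (s in seq_len(spec@scansPerSubject)) {
        k <- k + 1L
        sid <- if (spec@scansPerSubject == 1L) ph$id[i]
               else paste0(ph$id[i], "_r", s)
        tcs[[sid]] <- simulateTimecourses(ph[i, ], spec,
                                          seed = subSeed(spec@seed, 1000L + k),
                                          scanId = sid)
      }
    }
  }
  list(phenotypes = ph, timecourses = tcs)
}

# subject id of a scan id (strips the _r<k> repeat suffix)
scanSubject <- function(scanIds) sub("_r[0-9]+$", "", scanIds)
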