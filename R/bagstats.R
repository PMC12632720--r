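#' Compute brain-age gaps
#'
#' BAG = predicted age minus chronological age, exactly. One record per
#' subject, carrying the modality (sfnc/dfnc) and scope (wide or network
#' label) of the model that produced the prediction.
#'
#' @param predictions data.frame with columns \code{id} and
#'   \code{predicted_age} (or a named numeric vector of predictions).
#' @param phenotypes phenotype data.frame with columns \code{id}, \code{age}.
#' @param modality "sfnc" or "dfnc".
#' @param scope "wide" or a network label.
#' @return data.frame with columns id, modality, scope, predicted_age,
#'   chronological_age, bag.
#' @export
computeBAG <- function(predictions, phenotypes, modality, scope) {
  if (is.numeric(predictions))
    predictions <- data.frame(id = names(predictions),
                              predicted_age = unname(predictions))
  stopifnot(all(c("id", "predicted_age") %in% names(predictions)),
            all(c("id", "age") %in% names(phenotypes)))
  miss <- setdiff(predictions$id, phenotypes$id)
  if (length(miss))
    stop("predictions for unknown subject(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  m <- merge(predictions, phenotypes[, c("id", "age")], by = "id",
             sort = TRUE)
  data.frame(id = m$id, modality = modality, scope = scope,
             predicted_age = m$predicted_age, chronological_age = m$age,
             bag = m$predicted_age - m$age, stringsAsFactors = FALSE)
}

#' Association test specification
#'
#' Fixes the covariate scheme of every BAG-cognition test: age, sex, site,
#' age squared, the age-by-sex interaction and diagnosis, with the analysis
#' restricted to participants strictly older than \code{minAge} years.
#'
#' @param outcome "attention" or "working_memory".
#' @param minAge strict lower age bound (default 38; subjects with
#'   age > minAge are kept).
#' @return list of class "associationSpec".
#' @export
associationSpec <- function(outcome = c("attention", "working_memory"),
                            minAge = 38) {
  outcome <- match.arg(outcome)
  structure(list(outcome = outcome,
                 covariates = c("age", "sex", "site", "age2", "age_x_sex",
                                "dx"),
                 minAge = minAge),
            class = "associationSpec")
}

#' Fit one covariate-adjusted BAG-cognition association
#'
#' Ordinary least squares of the cognitive outcome on
#' [intercept, BAG, age, sex, site, age^2, age x sex, diagnosis], with site
#' dummy-coded against the lexicographically first site and age mean-centered
#' before squaring (a pure reparameterization that leaves the BAG
#' coefficient untouched). Reports the BAG coefficient with its SE, normal
#' 95% CI (beta +/- 1.96 SE), the partial correlation of outcome and BAG
#' given the covariates (\code{r = t / sqrt(t^2 + df)}), and the raw
#' two-sided p-value.
#'
#' @param bags BAG data.frame from [computeBAG()] for a single
#'   (modality, scope).
#' @param phenotypes phenotype data.frame (id, age, sex, site, dx and the
#'   outcome column).
#' @param spec an [associationSpec()].
#' @return one-row data.frame: outcome, modality, scope, beta, se, ci_low,
#'   ci_high, r, p_raw, n.
#' @export
fitAssociation <- function(bags, phenotypes, spec = associationSpec()) {
  stopifnot(inherits(spec, "associationSpec"))
  if (!nrow(bags)) stop("empty BAG table")
  if (length(unique(bags$modality)) != 1L ||
      length(unique(bags$scope)) != 1L)
    stop("fitAssociation expects a single (modality, scope); got several")
  d <- merge(bags[, c("id", "bag")], phenotypes, by = "id")
  d <- d[d$age > spec$minAge, , drop = FALSE]
  need <- c("bag", "age", "sex", "site", "dx", spec$outcome)
  d <- d[stats::complete.cases(d[, need]), , drop = FALSE]
  d$ageC <- d$age - mean(d$age)
  # hand-built design: treatment dummies against the lexicographically first
  # level; a one-level factor yields a constant column so the degenerate
  # case surfaces as a named singularity below, not a factor-contrast error
  dummyCols <- function(x, prefix) {
    lev <- sort(unique(as.character(x)))
    ref <- if (length(lev) > 1L) lev[-1L] else lev
    cols <- vapply(ref, function(l) as.numeric(x == l),
                   numeric(length(x)))
    cols <- matrix(cols, nrow = length(x),
                   dimnames = list(NULL, paste0(prefix, ref)))
    cols
  }
  sexD <- dummyCols(d$sex, "sex")
  siteD <- dummyCols(d$site, "site")
  dxD <- dummyCols(d$dx, "dx")
  X <- cbind("(Intercept)" = 1, bag = d$bag, ageC = d$ageC, sexD, siteD,
             "ageC2" = d$ageC^2, "ageC_x_sex" = d$ageC * sexD[, 1L], dxD)
  y <- d[[spec$outcome]]
  if (nrow(X) <= ncol(X) + 2L)
    stop("too few observations after the age > ", spec$minAge,
         " filter: n = ", nrow(X), " for ", ncol(X), " design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  df <- nrow(X) - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  beta <- fit$coefficients["bag"]
  seb <- se["bag"]
  tval <- beta / seb
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  r <- unname(tval / sqrt(tval^2 + df))
  data.frame(outcome = spec$outcome,
             modality = bags$modality[1L], scope = bags$scope[1L],
             beta = unname(beta), se = unname(seb),
             ci_low = unname(beta - 1.96 * seb),
             ci_high = unname(beta + 1.96 * seb),
             r = r, p_raw = unname(p), n = nrow(X),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values for one family of tests: monotone in the
#' sorted order, capped at 1, returned in the original order. Adjusted
#' values never fall below the raw ones.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhFDR(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
bhFDR <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the full BAG-cognition association suite
#'
#' For each outcome: the wide-brain family (sFNC and dFNC wBAGs, 2 tests,
#' FDR-corrected together) and the sub-network family (7 networks x 2
#' modalities = 14 tests, FDR-corrected together). The age filter is applied
#' inside every fit; raw and adjusted p-values are both reported.
#'
#' @param bags concatenated BAG data.frame from [computeBAG()] covering
#'   scopes "wide" plus every network, for both modalities.
#' @param phenotypes phenotype data.frame.
#' @param outcomes outcomes to test.
#' @param partition a [NetworkPartition-class] naming the expected networks.
#' @param minAge strict lower age bound for all fits.
#' @return data.frame with one row per test: outcome, family, modality,
#'   scope, beta, se, ci_low, ci_high, r, p_raw, p_fdr, n.
#' @export
runSuite <- function(bags, phenotypes,
                     outcomes = c("attention", "working_memory"),
                     partition = templatePartition(), minAge = 38) {
  if (is.null(bags) || !nrow(bags)) stop("empty BAG table")
  nets <- networkNames(partition)
  modalities <- c("sfnc", "dfnc")
  wanted <- rbind(
    expand.grid(modality = modalities, scope = "wide",
                family = "wide", stringsAsFactors = FALSE),
    expand.grid(modality = modalities, scope = nets,
                family = "subnetwork", stringsAsFactors = FALSE))
  have <- unique(bags[, c("modality", "scope")])
  missing <- !mapply(function(m, s) any(have$modality == m & have$scope == s),
                     wanted$modality, wanted$scope)
  if (any(missing))
    stop("missing BAGs for (modality, scope): ",
         paste(sprintf("(%s, %s)", wanted$modality[missing],
                       wanted$scope[missing]), collapse = ", "))
  out <- list()
  for (oc in outcomes) {
    spec <- associationSpec(oc, minAge = minAge)
    rows <- lapply(seq_len(nrow(wanted)), function(k) {
      b <- bags[bags$modality == wanted$modality[k] &
                  bags$scope == wanted$scope[k], , drop = FALSE]
      cbind(family = wanted$family[k],
            fitAssociation(b, phenotypes, spec))
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- NA_real_
    for (fam in c("wide", "subnetwork")) {
      idx <- tab$family == fam
      tab$p_fdr[idx] <- bhFDR(tab$p_raw[idx])
    }
    out[[oc]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("outcome", "family", "modality", "scope", "beta", "se",
          "ci_low", "ci_high", "r", "p_raw", "p_fdr", "n")]
}
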