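#' Additive allele-dosage matrix for one locus
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param locus locus name.
#' @return Integer matrix subjects x alleles with entries 0/1/2 copies;
#'   rows are all cohort subjects (NA across the row for subjects
#'   untyped at the locus). Row sums are 2 for typed subjects.
#' @export
dosageMatrix <- function(x, locus) {
  g <- genotypesAt(x, locus)
  if (nrow(g) == 0L) stop("no subject typed at locus ", locus)
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  ids <- subjectTable(x)$subject_id
  m <- matrix(NA_integer_, length(ids), length(alleles),
              dimnames = list(ids, alleles))
  i <- match(g$subject_id, ids)
  m[i, ] <- 0L
  m[cbind(i, match(g$allele1, alleles))] <-
    m[cbind(i, match(g$allele1, alleles))] + 1L
  m[cbind(i, match(g$allele2, alleles))] <-
    m[cbind(i, match(g$allele2, alleles))] + 1L
  m
}

#' Frequency and Hardy-Weinberg filtering of alleles
#'
#' Implements the pre-processing gate of the association analysis: an
#' allele enters model fitting only if its frequency is at least
#' \code{minFreq} and the exact Hardy-Weinberg test (allele vs all other
#' alleles of its locus pooled) does not reject at \code{hweAlpha} in
#' the designated stratum (controls by default, the standard QC
#' direction: alleles showing significant HWE deviation are excluded).
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param loci loci to process.
#' @param minFreq minimum overall allele frequency (default 0.02).
#' @param hweAlpha exclusion threshold for the exact HWE p-value
#'   (default 0.1; alleles with p below it are excluded).
#' @param hweGroup group in which HWE is tested (default
#'   \code{"CONTROL"}; \code{NULL} tests the full sample).
#' @return data.frame \code{locus}, \code{allele}, \code{frequency},
#'   \code{hwe_p}, \code{filter_status} (TESTED, EXCLUDED_FREQ or
#'   EXCLUDED_HWE).
#' @export
filterAlleles <- function(x, loci = HLA_CLASS_I, minFreq = 0.02,
                          hweAlpha = 0.1, hweGroup = "CONTROL") {
  s <- subjectTable(x)
  if (!is.null(hweGroup)) {
    strat <- s$subject_id[s$group == hweGroup]
    if (length(strat) == 0L)
      stop("no subjects in HWE stratum ", hweGroup)
  } else strat <- s$subject_id
  rows <- list()
  for (loc in intersect(loci, unique(genotypeTable(x)$locus))) {
    ac <- alleleCounts(x, loc)
    g <- genotypesAt(x, loc)
    gs <- g[g$subject_id %in% strat, ]
    for (k in seq_len(nrow(ac))) {
      a <- ac$allele[k]
      hweP <- if (nrow(gs)) {
        nAA <- sum(gs$allele1 == a & gs$allele2 == a)
        nAB <- sum(xor(gs$allele1 == a, gs$allele2 == a))
        hweExactTest(nAA, nAB, nrow(gs) - nAA - nAB)
      } else NA_real_
      status <- if (ac$frequency[k] < minFreq) "EXCLUDED_FREQ"
        else if (!is.na(hweP) && hweP < hweAlpha) "EXCLUDED_HWE"
        else "TESTED"
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, allele = a, frequency = ac$frequency[k],
        hwe_p = hweP, filter_status = status)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the additive logistic model for one term
#'
#' Fits \code{logit P(case) = b0 + b_d dosage + covariates} by maximum
#' likelihood and reports the Wald test on the dosage coefficient with a
#' 95\% confidence interval. Subjects with a missing dosage or covariate
#' are dropped from this model only. Non-convergence and separation
#' yield a NOT_CONVERGED result carrying no estimates.
#'
#' @param dosage numeric vector (0/1/2 allele copies or a category
#'   count).
#' @param case logical or 0/1 vector of case status.
#' @param age,sex optional covariate vectors (sex coded M/F or 0/1).
#' @param strata optional factor of cohort labels entered as fixed
#'   effects (dropped automatically when it has a single level).
#' @return One-row data.frame: \code{n_used}, \code{log_or}, \code{se},
#'   \code{or_}, \code{ci95_low}, \code{ci95_high}, \code{p_wald},
#'   \code{converged}.
#' @export
fitAdditiveGlm <- function(dosage, case, age = NULL, sex = NULL,
                           strata = NULL) {
  y <- as.numeric(case)
  stopifnot(all(y %in% c(0, 1), na.rm = TRUE))
  X <- cbind(`(Intercept)` = 1, dosage = as.numeric(dosage))
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age))
  if (!is.null(sex)) {
    sx <- if (is.character(sex) || is.factor(sex))
      as.numeric(as.character(sex) == "M") else as.numeric(sex)
    X <- cbind(X, sexM = sx)
  }
  if (!is.null(strata)) {
    strata <- droplevels(factor(strata))
    if (nlevels(strata) > 1L) {
      S <- stats::model.matrix(~strata)[, -1, drop = FALSE]
      colnames(S) <- paste0("cohort", levels(strata)[-1])
      X <- cbind(X, S)
    }
  }
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  nUsed <- length(y)
  notConv <- data.frame(n_used = nUsed, log_or = NA_real_, se = NA_real_,
                        or_ = NA_real_, ci95_low = NA_real_,
                        ci95_high = NA_real_, p_wald = NA_real_,
                        converged = FALSE)
  if (nUsed == 0L || length(unique(y)) < 2L ||
      length(unique(X[, "dosage"])) < 2L)
    return(notConv)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(notConv)
  p <- ncol(X)
  covmat <- tryCatch(chol2inv(fit$qr$qr[seq_len(p), seq_len(p),
                                        drop = FALSE]),
                     error = function(e) NULL)
  if (is.null(covmat)) return(notConv)
  b <- fit$coefficients["dosage"]
  se <- sqrt(diag(covmat))[match("dosage", colnames(X))]
  # separation: exploding estimate/uncertainty on the dosage term
  if (!is.finite(b) || !is.finite(se) || se > 50 || abs(b) > 15)
    return(notConv)
  z <- b / se
  data.frame(n_used = nUsed, log_or = unname(b), se = unname(se),
             or_ = exp(unname(b)),
             ci95_low = exp(unname(b) - 1.96 * se),
             ci95_high = exp(unname(b) + 1.96 * se),
             p_wald = 2 * pnorm(-abs(z)), converged = TRUE)
}

.comparisonSubset <- function(x, case, control) {
  s <- subjectTable(x)
  if (!any(s$group == case)) stop("no subjects in case group ", case)
  if (!any(s$group == control)) stop("no subjects in control group ", control)
  keep <- s$group %in% c(case, control)
  list(subjects = s[keep, , drop = FALSE],
       y = as.numeric(s$group[keep] == case))
}

.emptyEstimates <- function(n) data.frame(
  n_used = rep(NA_integer_, n), log_or = NA_real_, se = NA_real_,
  or_ = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
  p_wald = NA_real_, converged = NA)

#' Per-allele case-control association
#'
#' For each allele passing the frequency and Hardy-Weinberg filters,
#' fits the additive logistic model of case status on allele dosage with
#' age and sex covariates, independently per locus. Output is
#' volcano-ready (log odds ratio and -log10 p) and carries filter
#' provenance for excluded alleles. Significance is read at unadjusted
#' p < 0.05 with a Benjamini-Hochberg column for reference.
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param case,control group labels forming the comparison.
#' @param loci loci to scan (default class I).
#' @param minFreq,hweAlpha,hweGroup filter settings (see
#'   \code{\link{filterAlleles}}); \code{hweGroup} defaults to the
#'   control group of the comparison.
#' @param useCovariates include age and sex in the model (default TRUE).
#' @param strata optional cohort factor over subjects for pooled fits.
#' @return data.frame with one row per allele: term, comparison, counts,
#'   group frequencies, effect estimates, \code{p_wald}, \code{p_bh}
#'   (over tested terms), \code{neg_log10_p}, \code{hwe_p},
#'   \code{filter_status}.
#' @export
associateAlleles <- function(x, case = "CALR", control = "CONTROL",
                             loci = HLA_CLASS_I, minFreq = 0.02,
                             hweAlpha = 0.1, hweGroup = control,
                             useCovariates = TRUE, strata = NULL) {
  cmp <- .comparisonSubset(x, case, control)
  sub <- HlaCohort(cohortName(x), cmp$subjects,
                   genotypeTable(x)[genotypeTable(x)$subject_id %in%
                                      cmp$subjects$subject_id, ])
  filt <- filterAlleles(sub, loci, minFreq, hweAlpha, hweGroup)
  s <- subjectTable(sub)
  y <- as.numeric(s$group == case)
  if (!is.null(strata))
    strata <- strata[match(s$subject_id, subjectTable(x)$subject_id)]
  rows <- list()
  for (loc in unique(filt$locus)) {
    dm <- dosageMatrix(sub, loc)
    dm <- dm[s$subject_id, , drop = FALSE]
    fl <- filt[filt$locus == loc, ]
    for (k in seq_len(nrow(fl))) {
      a <- fl$allele[k]
      d <- dm[, a]
      freqCase <- mean(d[y == 1], na.rm = TRUE) / 2
      freqCtrl <- mean(d[y == 0], na.rm = TRUE) / 2
      est <- if (fl$filter_status[k] == "TESTED") {
        fitAdditiveGlm(d, y,
                       age = if (useCovariates) s$age else NULL,
                       sex = if (useCovariates) s$sex else NULL,
                       strata = strata)
      } else .emptyEstimates(1L)
      status <- fl$filter_status[k]
      if (status == "TESTED" && identical(est$converged, FALSE))
        status <- "NOT_CONVERGED"
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(term = a, locus = loc,
                   comparison = paste(case, "vs", control),
                   n_case = sum(y == 1), n_control = sum(y == 0),
                   freq_case = freqCase, freq_control = freqCtrl),
        est,
        data.frame(hwe_p = fl$hwe_p[k], filter_status = status))
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  tested <- out$filter_status == "TESTED"
  out$p_bh[tested] <- p.adjust(out$p_wald[tested], "BH")
  out$neg_log10_p <- -log10(out$p_wald)
  rownames(out) <- NULL
  out
}

#' Binder-category case-control association
#'
#' Alternative to per-allele testing: each subject's six class I allele
#' copies are counted into strong/weak/non-binder categories per
#' mutation (dosage 0..6), and the same additive logistic model is fit
#' per category term. As in the source analysis, no frequency or HWE
#' exclusion applies here; zero-variance terms are flagged.
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param annotations data.frame \code{allele}, \code{mutation_id},
#'   \code{category} (SB/WB/NB) covering every class I allele in the
#'   cohort, e.g. from \code{\link{categorizeBinder}} over
#'   \code{\link{alleleBestRanks}}.
#' @param case,control group labels.
#' @param useCovariates include age and sex (default TRUE).
#' @param strata optional cohort factor for pooled fits.
#' @return data.frame as \code{\link{associateAlleles}}, with terms like
#'   \code{"CALRmut_SB"}.
#' @export
associateCategories <- function(x, annotations, case = "CALR",
                                control = "CONTROL", useCovariates = TRUE,
                                strata = NULL) {
  cmp <- .comparisonSubset(x, case, control)
  s <- cmp$subjects
  y <- cmp$y
  g <- genotypeTable(x)
  g <- g[g$subject_id %in% s$subject_id & g$locus %in% HLA_CLASS_I, ]
  alleles <- unique(c(g$allele1, g$allele2))
  if (!is.null(strata))
    strata <- strata[match(s$subject_id,
                           subjectTable(x)$subject_id)]
  rows <- list()
  for (m in unique(annotations$mutation_id)) {
    ann <- annotations[annotations$mutation_id == m, ]
    unknown <- setdiff(alleles, ann$allele)
    if (length(unknown))
      stop("unannotated allele(s) for ", m, ": ",
           paste(unknown, collapse = ", "))
    cat6 <- setNames(as.character(ann$category), ann$allele)
    for (lev in c("SB", "WB", "NB")) {
      d <- vapply(s$subject_id, function(sid) {
        gi <- g[g$subject_id == sid, ]
        if (length(unique(gi$locus)) < 3L) return(NA_real_)
        copies <- c(gi$allele1, gi$allele2)
        sum(cat6[copies] == lev)
      }, 0)
      est <- fitAdditiveGlm(d, y,
                            age = if (useCovariates) s$age else NULL,
                            sex = if (useCovariates) s$sex else NULL,
                            strata = strata)
      status <- if (length(unique(d[!is.na(d)])) < 2L) "NOT_CONVERGED"
        else if (identical(est$converged, FALSE)) "NOT_CONVERGED"
        else "TESTED"
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(term = paste0(m, "_", lev), locus = NA_character_,
                   comparison = paste(case, "vs", control),
                   n_case = sum(y == 1), n_control = sum(y == 0),
                   freq_case = mean(d[y == 1], na.rm = TRUE) / 6,
                   freq_control = mean(d[y == 0], na.rm = TRUE) / 6),
        est,
        data.frame(hwe_p = NA_real_, filter_status = status))
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  tested <- out$filter_status == "TESTED"
  out$p_bh[tested] <- p.adjust(out$p_wald[tested], "BH")
  out$neg_log10_p <- -log10(out$p_wald)
  rownames(out) <- NULL
  out
}
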