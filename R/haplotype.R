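# Enumerate the diplotype expansions of one subject's unphased genotype
# across the requested loci. Returns a list of (hap1, hap2) character
# pairs; the first heterozygous locus is phase-anchored so each
# unordered diplotype appears once.
.diplotypeExpansions <- function(a1, a2) {
  het <- which(a1 != a2)
  if (length(het) == 0L) {
    hap <- paste(a1, collapse = "-")
    return(list(c(hap, hap)))
  }
  flip <- het[-1]
  combos <- if (length(flip))
    expand.grid(rep(list(c(FALSE, TRUE)), length(flip)),
                KEEP.OUT.ATTRS = FALSE) else data.frame(row.names = 1)
  lapply(seq_len(nrow(combos)), function(r) {
    h1 <- a1; h2 <- a2
    for (j in seq_along(flip)) {
      if (combos[r, j]) {
        k <- flip[j]
        tmp <- h1[k]; h1[k] <- h2[k]; h2[k] <- tmp
      }
    }
    c(paste(h1, collapse = "-"), paste(h2, collapse = "-"))
  })
}

# Per-subject expansion table for a cohort: list with per-subject index
# vectors into the haplotype universe.
.expandCohort <- function(x, loci, maxExpansions) {
  g <- genotypeTable(x)
  g <- g[g$locus %in% loci, ]
  wide <- lapply(loci, function(loc) {
    gl <- g[g$locus == loc, ]
    gl[match(subjectTable(x)$subject_id, gl$subject_id),
       c("allele1", "allele2")]
  })
  typed <- Reduce(`&`, lapply(wide, function(w) !is.na(w$allele1)))
  ids <- subjectTable(x)$subject_id[typed]
  if (length(ids) == 0L) stop("no subject typed at all requested loci")
  expansions <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    row <- which(typed)[i]
    a1 <- vapply(wide, function(w) w$allele1[row], "")
    a2 <- vapply(wide, function(w) w$allele2[row], "")
    exp_i <- .diplotypeExpansions(a1, a2)
    if (length(exp_i) > maxExpansions)
      stop("diplotype expansion cap exceeded for subject ", ids[i])
    expansions[[i]] <- exp_i
  }
  names(expansions) <- ids
  expansions
}

#' EM estimation of multi-locus haplotype frequencies
#'
#' Estimates haplotype frequencies from unphased genotypes by
#' expectation-maximisation under random mating: the E-step distributes
#' each subject over the diplotypes consistent with their genotype in
#' proportion to products of current haplotype frequencies, the M-step
#' re-estimates frequencies from expected haplotype counts. Frequencies
#' are initialised at products of marginal allele frequencies (a
#' deterministic start that also resolves likelihood ties), and the
#' log-likelihood is non-decreasing across iterations.
#'
#' @param x an \linkS4class{HlaCohort}; subjects untyped at any
#'   requested locus are dropped.
#' @param loci ordered character vector of 2-4 loci.
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @param pruneFreq haplotypes below this frequency are dropped from the
#'   report and the remainder renormalised (default 1e-6).
#' @param maxExpansions per-subject safety cap on diplotype expansions.
#' @return A \code{HaplotypeFreqs} list: \code{loci}, \code{freq} (named,
#'   sums to 1), \code{logLik} (trace), \code{n_used},
#'   \code{expectedDosage} (subjects x haplotypes matrix of posterior
#'   expected copies, before pruning), \code{converged}.
#' @export
emHaplotypeFrequencies <- function(x, loci, tol = 1e-8, maxIter = 1000L,
                                   pruneFreq = 1e-6,
                                   maxExpansions = 4096L) {
  stopifnot(is(x, "HlaCohort"), length(loci) >= 2L, length(loci) <= 4L,
            all(loci %in% HLA_LOCI))
  expansions <- .expandCohort(x, loci, maxExpansions)
  n <- length(expansions)
  haps <- sort(unique(unlist(expansions)))
  H <- length(haps)
  # initial frequencies: product of marginal allele frequencies
  parts <- strsplit(haps, "-", fixed = TRUE)
  f <- rep(1, H)
  sub <- HlaCohort(cohortName(x),
                   subjectTable(x)[subjectTable(x)$subject_id %in%
                                     names(expansions), ],
                   genotypeTable(x)[genotypeTable(x)$subject_id %in%
                                      names(expansions), ])
  for (j in seq_along(loci)) {
    aj <- vapply(parts, `[`, "", j)
    ac <- alleleCounts(sub, loci[j])
    f <- f * ac$frequency[match(aj, ac$allele)]
  }
  f <- f / sum(f)
  # flatten expansions once: one row per candidate diplotype
  nExp <- lengths(expansions)
  subjIdx <- rep.int(seq_len(n), nExp)
  flat <- unlist(expansions, use.names = FALSE)
  i1 <- match(flat[c(TRUE, FALSE)], haps)
  i2 <- match(flat[c(FALSE, TRUE)], haps)
  mult <- ifelse(i1 == i2, 1, 2)
  logLik <- numeric(0)
  converged <- FALSE
  normW <- NULL
  for (iter in seq_len(maxIter)) {
    w <- f[i1] * f[i2] * mult
    tw <- rowsum(w, subjIdx)[, 1L]
    logLik <- c(logLik, sum(log(tw)))
    normW <- w / tw[subjIdx]
    if (iter > 1L && logLik[iter] - logLik[iter - 1L] < tol) {
      converged <- TRUE
      break
    }
    cnt <- rowsum(c(normW, normW), c(i1, i2))
    counts <- numeric(H)
    counts[as.integer(rownames(cnt))] <- cnt[, 1L]
    f <- counts / (2 * n)
  }
  # posterior expected dosage per subject under the final frequencies
  dosage <- matrix(0, n, H, dimnames = list(names(expansions), haps))
  for (r in seq_along(subjIdx)) {
    dosage[subjIdx[r], i1[r]] <- dosage[subjIdx[r], i1[r]] + normW[r]
    dosage[subjIdx[r], i2[r]] <- dosage[subjIdx[r], i2[r]] + normW[r]
  }
  keep <- f >= pruneFreq
  freq <- f[keep] / sum(f[keep])
  names(freq) <- haps[keep]
  structure(list(loci = loci, freq = freq, logLik = logLik,
                 n_used = n, expectedDosage = dosage,
                 converged = converged),
            class = "HaplotypeFreqs")
}

#' @export
print.HaplotypeFreqs <- function(x, ...) {
  cat("HaplotypeFreqs over", paste(x$loci, collapse = "-"), ":",
      length(x$freq), "haplotypes from", x$n_used, "subjects;",
      length(x$logLik), "EM iterations\n")
  top <- sort(x$freq, decreasing = TRUE)
  print(round(head(top, 8L), 4))
  invisible(x)
}

#' Score tests on imputed haplotype dosages
#'
#' For each haplotype retained above \code{pruneFreq}, computes the
#' posterior expected dosage per subject from the EM fit and tests its
#' association with case status by the efficient score of the logistic
#' model, with age and sex fitted under the null (so no per-haplotype
#' refit is required). The score variance accounts for the estimated
#' nuisance parameters.
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param loci loci of the haplotype system.
#' @param case,control group labels forming the comparison.
#' @param useCovariates adjust for age and sex (default TRUE; subjects
#'   missing either are dropped).
#' @param pruneFreq minimum estimated frequency for a haplotype to be
#'   tested (default 0.01, reporting only non-rare haplotypes).
#' @param ... passed to \code{\link{emHaplotypeFrequencies}}.
#' @return data.frame \code{haplotype}, \code{freq}, \code{score}
#'   (signed z), \code{beta_onestep}, \code{p}, \code{n_used}.
#' @export
haplotypeScoreTest <- function(x, loci, case = "CALR",
                               control = "CONTROL", useCovariates = TRUE,
                               pruneFreq = 0.01, ...) {
  cmp <- .comparisonSubset(x, case, control)
  sub <- HlaCohort(cohortName(x), cmp$subjects,
                   genotypeTable(x)[genotypeTable(x)$subject_id %in%
                                      cmp$subjects$subject_id, ])
  em <- emHaplotypeFrequencies(sub, loci, ...)
  s <- subjectTable(sub)
  i <- match(rownames(em$expectedDosage), s$subject_id)
  y <- as.numeric(s$group[i] == case)
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if (useCovariates) {
    X <- cbind(X, age = s$age[i],
               sexM = as.numeric(s$sex[i] == "M"))
  }
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  D <- em$expectedDosage[keep, , drop = FALSE]
  fit <- glm.fit(X, y, family = binomial())
  if (!fit$converged) stop("null covariate model did not converge")
  p0 <- fit$fitted.values
  w <- p0 * (1 - p0)
  XtWXinv <- solve(crossprod(X * w, X))
  tested <- names(em$freq)[em$freq >= pruneFreq]
  rows <- lapply(tested, function(h) {
    d <- D[, h]
    U <- sum(d * (y - p0))
    dW <- d * w
    V <- sum(d * dW) - drop(crossprod(dW, X) %*% XtWXinv %*%
                              crossprod(X, dW))
    if (V <= 0) return(NULL)
    z <- U / sqrt(V)
    data.frame(haplotype = h, freq = unname(em$freq[h]), score = z,
               beta_onestep = U / V, p = 2 * pnorm(-abs(z)),
               n_used = length(y))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(haplotype = character(), freq = numeric(),
                      score = numeric(), beta_onestep = numeric(),
                      p = numeric(), n_used = integer())
  rownames(out) <- NULL
  out
}

#' Haplotype association scan over locus combinations
#'
#' Runs \code{\link{haplotypeScoreTest}} for every combination of the
#' requested arities within one HLA class (class I: 3 loci, so e.g.
#' arity 2 gives 3 pairs; class II: 4 loci). Subjects missing any locus
#' of a combination are dropped for that combination only.
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param hlaClass \code{"I"} or \code{"II"}.
#' @param arities subset of \code{c(2, 3, 4)}.
#' @param case,control group labels.
#' @param ... passed to \code{\link{haplotypeScoreTest}}.
#' @return Combined data.frame with \code{loci}, \code{haplotype},
#'   \code{freq}, \code{score}, \code{p}, \code{neg_log10_p},
#'   \code{n_used}.
#' @export
haplotypeAssociationScan <- function(x, hlaClass = c("I", "II"),
                                     arities = c(2L, 3L),
                                     case = "CALR", control = "CONTROL",
                                     ...) {
  hlaClass <- match.arg(hlaClass)
  lociAll <- if (hlaClass == "I") HLA_CLASS_I else HLA_CLASS_II
  arities <- intersect(as.integer(arities), 2:4)
  rows <- list()
  for (ar in arities) {
    if (ar > length(lociAll)) next
    combos <- combn(lociAll, ar)
    for (cc in seq_len(ncol(combos))) {
      loci <- combos[, cc]
      res <- haplotypeScoreTest(x, loci, case, control, ...)
      if (nrow(res)) {
        res$loci <- paste(loci, collapse = "-")
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$neg_log10_p <- -log10(out$p)
  out[, c("loci", "haplotype", "freq", "score", "beta_onestep", "p",
          "neg_log10_p", "n_used")]
}
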