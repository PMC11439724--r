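#' Pool cohorts into one labelled sample
#'
#' Concatenates cohorts for a combined analysis, keeping the cohort
#' label per subject. Subject ids are prefixed with their cohort name
#' whenever an id occurs in more than one cohort, so ids stay unique.
#'
#' @param cohorts list of \linkS4class{HlaCohort}s (at least two).
#' @param name label for the pooled cohort.
#' @return An \linkS4class{HlaCohort} whose subject table's
#'   \code{cohort} column preserves the origin of each subject.
#' @export
poolCohorts <- function(cohorts, name = "pooled") {
  stopifnot(length(cohorts) >= 2L,
            all(vapply(cohorts, is, TRUE, "HlaCohort")))
  subj <- lapply(cohorts, subjectTable)
  geno <- lapply(cohorts, genotypeTable)
  for (i in seq_along(cohorts)) {
    subj[[i]]$cohort <- cohortName(cohorts[[i]])
  }
  allIds <- unlist(lapply(subj, `[[`, "subject_id"))
  dup <- unique(allIds[duplicated(allIds)])
  if (length(dup)) {
    for (i in seq_along(cohorts)) {
      hit <- subj[[i]]$subject_id %in% dup
      newId <- paste0(cohortName(cohorts[[i]]), ".",
                      subj[[i]]$subject_id)
      gHit <- geno[[i]]$subject_id %in% subj[[i]]$subject_id[hit]
      geno[[i]]$subject_id[gHit] <-
        paste0(cohortName(cohorts[[i]]), ".", geno[[i]]$subject_id[gHit])
      subj[[i]]$subject_id[hit] <- newId[hit]
    }
  }
  HlaCohort(name, do.call(rbind, subj), do.call(rbind, geno))
}

#' Pooled multi-cohort allele association
#'
#' Runs the additive allele association on a pooled sample with
#' fixed-effect cohort indicators in the model (in addition to age and
#' sex where available), so that allele-frequency differences between
#' cohorts cannot masquerade as case-control effects. With a single
#' cohort the indicator drops automatically and the result equals
#' \code{\link{associateAlleles}} on that cohort. Per-cohort stratified
#' estimates are attached for transparency.
#'
#' @param x a pooled \linkS4class{HlaCohort} (see
#'   \code{\link{poolCohorts}}).
#' @param case,control group labels (e.g. \code{"CALR"} vs
#'   \code{"JAK2"}).
#' @param ... passed to \code{\link{associateAlleles}}.
#' @return data.frame as \code{\link{associateAlleles}}; attribute
#'   \code{stratified} holds a list of per-cohort result tables.
#' @export
pooledAssociation <- function(x, case = "CALR", control = "JAK2", ...) {
  s <- subjectTable(x)
  strata <- factor(s$cohort)
  out <- associateAlleles(x, case, control, strata = strata, ...)
  perCohort <- list()
  for (cn in levels(strata)) {
    sc <- s[s$cohort == cn, ]
    if (!any(sc$group == case) || !any(sc$group == control)) next
    sub <- HlaCohort(cn, sc,
                     genotypeTable(x)[genotypeTable(x)$subject_id %in%
                                        sc$subject_id, ])
    perCohort[[cn]] <- tryCatch(associateAlleles(sub, case, control, ...),
                                error = function(e) NULL)
  }
  attr(out, "stratified") <- perCohort
  out
}

#' Cross-mutation PHBR correlation per group
#'
#' Tests, within each subject group, the Pearson correlation between a
#' subject's PHBR for one mutation and for the other (two-sided p from
#' the t-distribution transform). An inverse correlation means
#' genotypes good at presenting one driver mutation's neoantigens tend
#' to be poor at presenting the other's.
#'
#' @param phbrTab long PHBR table from \code{\link{cohortPhbrTable}}
#'   covering exactly two mutation ids.
#' @param groups named character vector or data.frame
#'   (\code{subject_id}, \code{group}) assigning each subject to a
#'   correlation group (e.g. cohort x status, or super-region).
#' @param log10Scale correlate log10 PHBRs instead of raw values
#'   (default FALSE).
#' @return data.frame \code{group}, \code{n}, \code{r}, \code{p} for
#'   every group with at least three complete subjects.
#' @export
phbrCorrelation <- function(phbrTab, groups, log10Scale = FALSE) {
  muts <- unique(phbrTab$mutation_id)
  if (length(muts) != 2L)
    stop("phbrCorrelation needs exactly two mutation ids, got: ",
         paste(muts, collapse = ", "))
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$group), groups$subject_id)
  w1 <- phbrTab[phbrTab$mutation_id == muts[1], ]
  w2 <- phbrTab[phbrTab$mutation_id == muts[2], ]
  ids <- intersect(w1$subject_id, w2$subject_id)
  v1 <- w1$phbr[match(ids, w1$subject_id)]
  v2 <- w2$phbr[match(ids, w2$subject_id)]
  if (log10Scale) { v1 <- log10(v1); v2 <- log10(v2) }
  gr <- groups[ids]
  rows <- list()
  for (g in sort(unique(na.omit(gr)))) {
    i <- which(gr == g)
    if (length(i) < 3L) next
    if (sd(v1[i]) == 0 || sd(v2[i]) == 0)
      stop("zero-variance PHBR vector in group ", g)
    ct <- cor.test(v1[i], v2[i], method = "pearson",
                   alternative = "two.sided")
    rows[[g]] <- data.frame(group = g, n = length(i),
                            r = unname(ct$estimate), p = ct$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
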