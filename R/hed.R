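#' HLA evolutionary divergence of one allele pair
#'
#' HED between two aligned binding-groove sequences is the mean Grantham
#' distance over positions: the per-site distances of the residue pairs
#' summed and divided by the sequence length. It is zero for identical
#' sequences (hence for homozygous loci) and grows with the structural
#' divergence of the two encoded molecules, i.e. with the breadth of the
#' peptide repertoire the locus can present.
#'
#' @param seq1,seq2 equal-length amino-acid strings.
#' @return Non-negative scalar.
#' @export
locusHed <- function(seq1, seq2) {
  seq1 <- as.character(seq1); seq2 <- as.character(seq2)
  if (nchar(seq1) != nchar(seq2))
    stop("sequences must have equal length (", nchar(seq1), " vs ",
         nchar(seq2), ")")
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  mean(granthamDistance(a, b))
}

#' Per-subject HED across loci with class means
#'
#' For every subject and typed locus, the HED of the two alleles'
#' binding-groove sequences; homozygous loci short-circuit to zero
#' without a sequence lookup. The class I mean averages A, B and C, the
#' class II mean averages DPB1, DQA1, DQB1 and DRB1; a class mean is
#' reported only when all of its constituent loci are evaluable (typed,
#' and for heterozygotes with both sequences present in \code{db}).
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param db an \linkS4class{AlleleSequenceDB}.
#' @return data.frame with \code{subject_id}, one \code{hed_<locus>}
#'   column per locus, \code{mean_class_I}, \code{mean_class_II}.
#'   Attribute \code{flagged} lists (subject, locus) pairs omitted for
#'   missing sequences.
#' @export
cohortHed <- function(x, db) {
  stopifnot(is(x, "HlaCohort"), is(db, "AlleleSequenceDB"))
  ids <- subjectTable(x)$subject_id
  g <- genotypeTable(x)
  out <- data.frame(subject_id = ids)
  for (loc in HLA_LOCI) out[[paste0("hed_", loc)]] <- NA_real_
  flagged <- list()
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    col <- paste0("hed_", row$locus)
    j <- match(row$subject_id, ids)
    if (row$allele1 == row$allele2) {          # homozygous: zero by definition
      out[[col]][j] <- 0
      next
    }
    s1 <- alleleSequence(db, row$allele1)
    s2 <- alleleSequence(db, row$allele2)
    if (is.na(s1) || is.na(s2)) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        subject_id = row$subject_id, locus = row$locus,
        reason = "missing allele sequence")
      next
    }
    out[[col]][j] <- locusHed(s1, s2)
  }
  hedI <- as.matrix(out[paste0("hed_", HLA_CLASS_I)])
  hedII <- as.matrix(out[paste0("hed_", HLA_CLASS_II)])
  out$mean_class_I <- ifelse(rowSums(is.na(hedI)) == 0L,
                             rowMeans(hedI), NA_real_)
  out$mean_class_II <- ifelse(rowSums(is.na(hedII)) == 0L,
                              rowMeans(hedII), NA_real_)
  attr(out, "flagged") <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(subject_id = character(), locus = character(),
               reason = character())
  out
}

#' Compare HED between disease groups
#'
#' Per-group summary of an HED measure with pairwise Welch two-sided
#' t-tests, the comparison used to ask whether genotype diversity
#' differs between mutation carriers and controls.
#'
#' @param hed output of \code{\link{cohortHed}}.
#' @param groups character vector parallel to \code{hed$subject_id}
#'   giving each subject's group, or an \linkS4class{HlaCohort} from
#'   which groups are taken by subject id.
#' @param measure column of \code{hed} to compare (e.g.
#'   \code{"mean_class_I"} or \code{"hed_DQB1"}).
#' @return A list with \code{summary} (per group: n, mean, sd) and
#'   \code{tests} (group1, group2, p from Welch's t-test).
#' @export
hedGroupComparison <- function(hed, groups, measure = "mean_class_I") {
  if (is(groups, "HlaCohort")) {
    s <- subjectTable(groups)
    groups <- s$group[match(hed$subject_id, s$subject_id)]
  }
  stopifnot(measure %in% names(hed), length(groups) == nrow(hed))
  v <- hed[[measure]]
  keep <- !is.na(v) & !is.na(groups)
  v <- v[keep]; groups <- as.character(groups)[keep]
  gl <- sort(unique(groups))
  if (length(gl) < 2L) stop("need at least two groups")
  n <- vapply(gl, function(g) sum(groups == g), 0L)
  if (any(n < 2L))
    stop("group(s) with fewer than two subjects: ",
         paste(gl[n < 2L], collapse = ", "))
  summary <- data.frame(group = gl, n = n,
                        mean = vapply(gl, function(g) mean(v[groups == g]), 0),
                        sd = vapply(gl, function(g) sd(v[groups == g]), 0),
                        row.names = NULL)
  pairs <- utils::combn(gl, 2L)
  tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      p = apply(pairs, 2L, function(pr)
                        t.test(v[groups == pr[1]], v[groups == pr[2]])$p.value))
  list(summary = summary, tests = tests)
}
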