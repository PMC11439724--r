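setOldClass("data.frame")

#' HlaCohort: subjects, groups and unphased HLA genotypes
#'
#' Container for a case-control cohort typed at up to seven HLA loci at
#' two-field resolution. Allele pairs per locus are unordered; loci may be
#' missing per subject (a locus with only one known allele is dropped at
#' read time rather than treated as homozygous).
#'
#' @slot name cohort label.
#' @slot subjects data.frame with columns \code{subject_id},
#'   \code{cohort}, \code{group} (CALR, JAK2 or CONTROL), \code{age},
#'   \code{sex} (M/F, may be NA).
#' @slot genotypes long data.frame with columns \code{subject_id},
#'   \code{locus}, \code{allele1}, \code{allele2} (canonical two-field
#'   names, stored with allele1 <= allele2 so comparison ignores input
#'   order).
#'
#' @aliases HlaCohort
#' @exportClass HlaCohort
setClass("HlaCohort",
  representation(name = "character", subjects = "data.frame",
                 genotypes = "data.frame"))

setValidity("HlaCohort", function(object) {
  s <- object@subjects
  g <- object@genotypes
  need <- c("subject_id", "cohort", "group", "age", "sex")
  if (!all(need %in% names(s)))
    return(paste("subjects must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$subject_id))
    return("duplicate subject_id in cohort")
  if (!all(s$group %in% c("CALR", "JAK2", "CONTROL")))
    return("group must be one of CALR, JAK2, CONTROL")
  age <- s$age[!is.na(s$age)]
  if (length(age) && (any(age < 0) || any(age > 120)))
    return("age must lie in [0, 120]")
  if (!all(is.na(s$sex) | s$sex %in% c("M", "F")))
    return("sex must be M, F or NA")
  gneed <- c("subject_id", "locus", "allele1", "allele2")
  if (!all(gneed %in% names(g)))
    return(paste("genotypes must have columns:", paste(gneed, collapse = ", ")))
  if (nrow(g)) {
    if (!all(g$locus %in% HLA_LOCI)) return("unknown locus in genotypes")
    if (!all(g$subject_id %in% s$subject_id))
      return("genotype rows for unknown subject_id")
    if (anyDuplicated(g[, c("subject_id", "locus")]))
      return("more than one genotype row per subject and locus")
    if (!all(g$allele1 <= g$allele2))
      return("genotype allele pairs must be stored in sorted order")
    loc1 <- sub("\\*.*$", "", g$allele1)
    loc2 <- sub("\\*.*$", "", g$allele2)
    if (!all(loc1 == g$locus & loc2 == g$locus))
      return("allele locus does not match genotype locus column")
  }
  TRUE
})

#' Construct an HlaCohort
#'
#' @param name cohort label.
#' @param subjects subject table (see \linkS4class{HlaCohort}).
#' @param genotypes long genotype table; allele strings are parsed and
#'   canonicalised, and each pair is stored order-free.
#' @return An \linkS4class{HlaCohort}.
#' @export
HlaCohort <- function(name, subjects, genotypes) {
  subjects <- as.data.frame(subjects)
  genotypes <- as.data.frame(genotypes)
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  subjects$sex <- as.character(subjects$sex)
  subjects$age <- as.numeric(subjects$age)
  if (nrow(genotypes)) {
    genotypes$subject_id <- as.character(genotypes$subject_id)
    a1 <- parseHlaAllele(genotypes$allele1)$allele
    a2 <- parseHlaAllele(genotypes$allele2)$allele
    genotypes$allele1 <- pmin(a1, a2)
    genotypes$allele2 <- pmax(a1, a2)
  }
  rownames(subjects) <- NULL
  rownames(genotypes) <- NULL
  new("HlaCohort", name = as.character(name), subjects = subjects,
      genotypes = genotypes)
}

#' @describeIn HlaCohort-class cohort label.
#' @param object,x an \code{HlaCohort}.
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @export
setMethod("cohortName", "HlaCohort", function(x) x@name)

#' @describeIn HlaCohort-class subject metadata table.
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))

#' @export
setMethod("subjectTable", "HlaCohort", function(x) x@subjects)

#' @describeIn HlaCohort-class long genotype table.
#' @export
setGeneric("genotypeTable", function(x) standardGeneric("genotypeTable"))

#' @export
setMethod("genotypeTable", "HlaCohort", function(x) x@genotypes)

#' @describeIn HlaCohort-class number of subjects.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @export
setMethod("nSubjects", "HlaCohort", function(x) nrow(x@subjects))

#' @describeIn HlaCohort-class subject counts per disease group.
#' @export
setGeneric("groupCounts", function(x) standardGeneric("groupCounts"))

#' @export
setMethod("groupCounts", "HlaCohort", function(x) {
  tab <- table(factor(x@subjects$group, c("CALR", "JAK2", "CONTROL")))
  setNames(as.integer(tab), names(tab))
})

setMethod("show", "HlaCohort", function(object) {
  gc <- groupCounts(object)
  cat("HlaCohort \"", object@name, "\": ", nrow(object@subjects),
      " subjects (CALR ", gc["CALR"], ", JAK2 ", gc["JAK2"],
      ", CONTROL ", gc["CONTROL"], ")\n", sep = "")
  cat("  typed loci:",
      paste(intersect(HLA_LOCI, unique(object@genotypes$locus)),
            collapse = ", "), "\n")
})

#' Genotypes of one locus
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param locus a locus name.
#' @return data.frame \code{subject_id}, \code{allele1}, \code{allele2}
#'   restricted to subjects typed at \code{locus}.
#' @export
genotypesAt <- function(x, locus) {
  stopifnot(is(x, "HlaCohort"), locus %in% HLA_LOCI)
  g <- x@genotypes[x@genotypes$locus == locus,
                   c("subject_id", "allele1", "allele2")]
  rownames(g) <- NULL
  g
}

#' Distinct alleles observed in a cohort
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param loci loci to include (default all).
#' @return Sorted character vector of canonical allele names.
#' @export
cohortAlleles <- function(x, loci = HLA_LOCI) {
  g <- x@genotypes[x@genotypes$locus %in% loci, ]
  sort(unique(c(g$allele1, g$allele2)))
}

#' AlleleSequenceDB: binding-groove protein sequences per allele
#'
#' Maps two-field HLA alleles to the amino-acid sequence of the
#' peptide-binding domain used for evolutionary-divergence calculations.
#' All sequences of one locus have equal length and contain only the 20
#' standard residues.
#'
#' @slot sequences a \link[Biostrings]{AAStringSet} named by canonical
#'   allele.
#' @slot locus character vector parallel to \code{sequences}.
#' @exportClass AlleleSequenceDB
setClass("AlleleSequenceDB",
  representation(sequences = "AAStringSet", locus = "character"))

setValidity("AlleleSequenceDB", function(object) {
  n <- length(object@sequences)
  if (length(object@locus) != n)
    return("locus vector must parallel sequences")
  if (n == 0L) return(TRUE)
  if (is.null(names(object@sequences)) ||
      anyDuplicated(names(object@sequences)))
    return("sequences must be uniquely named by allele")
  if (!all(object@locus %in% HLA_LOCI)) return("unknown locus")
  letters_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$",
                      as.character(object@sequences))
  if (!all(letters_ok))
    return("sequences must contain only the 20 standard residues")
  w <- Biostrings::width(object@sequences)
  for (loc in unique(object@locus)) {
    if (length(unique(w[object@locus == loc])) > 1L)
      return(paste0("unequal sequence lengths at locus ", loc))
  }
  TRUE
})

#' Construct an AlleleSequenceDB from named sequences
#'
#' @param sequences named character vector or AAStringSet; names are
#'   allele strings (any resolution; truncated to two fields).
#' @return An \linkS4class{AlleleSequenceDB}.
#' @export
AlleleSequenceDB <- function(sequences) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  parsed <- parseHlaAllele(names(sequences))
  names(sequences) <- parsed$allele
  if (anyDuplicated(parsed$allele))
    stop("duplicate two-field alleles in sequence set")
  new("AlleleSequenceDB", sequences = sequences, locus = parsed$locus)
}

#' @describeIn AlleleSequenceDB-class alleles present in the database.
#' @param x an \code{AlleleSequenceDB}.
#' @export
dbAlleles <- function(x) names(x@sequences)

#' Look up allele sequences
#'
#' @param x an \linkS4class{AlleleSequenceDB}.
#' @param allele canonical allele names.
#' @return Character vector of sequences (NA where absent).
#' @export
alleleSequence <- function(x, allele) {
  out <- rep(NA_character_, length(allele))
  hit <- match(allele, names(x@sequences))
  out[!is.na(hit)] <- as.character(x@sequences[hit[!is.na(hit)]])
  out
}

setMethod("show", "AlleleSequenceDB", function(object) {
  cat("AlleleSequenceDB:", length(object@sequences), "alleles across",
      length(unique(object@locus)), "loci\n")
  for (loc in intersect(HLA_LOCI, unique(object@locus))) {
    i <- object@locus == loc
    cat(sprintf("  %-5s %3d alleles, length %d\n", loc, sum(i),
                unique(Biostrings::width(object@sequences[i]))))
  }
})

#' PeptideSet: enumerated mutant k-mer windows for one mutation
#'
#' Windows are positional: the same peptide string occurring at two starts
#' is kept twice, so window counts match sliding-window arithmetic. A
#' deduplicated string view for predictor submission is available through
#' \code{peptides()}.
#'
#' @slot mutationId mutation label, e.g. \code{"CALRmut"}.
#' @slot context amino-acid context the windows were cut from.
#' @slot windows data.frame \code{start} (1-based), \code{length},
#'   \code{peptide}.
#' @slot kRange inclusive length bounds used for enumeration.
#' @exportClass PeptideSet
setClass("PeptideSet",
  representation(mutationId = "character", context = "character",
                 windows = "data.frame", kRange = "integer"))

setValidity("PeptideSet", function(object) {
  w <- object@windows
  if (!all(c("start", "length", "peptide") %in% names(w)))
    return("windows needs start, length, peptide")
  if (nrow(w)) {
    if (any(w$length < object@kRange[1]) || any(w$length > object@kRange[2]))
      return("window length outside kRange")
    cut <- substring(object@context, w$start, w$start + w$length - 1L)
    if (!all(cut == w$peptide))
      return("window peptide does not match context at its coordinates")
    if (anyDuplicated(w[, c("start", "length")]))
      return("duplicate (start, length) window")
    if (!identical(order(w$start, w$length), seq_len(nrow(w))))
      return("windows must be position-ordered")
  }
  TRUE
})

#' @describeIn PeptideSet-class number of positional windows.
#' @param x a \code{PeptideSet}.
#' @export
windowCount <- function(x) nrow(x@windows)

#' @describeIn PeptideSet-class the positional window table.
#' @export
windowTable <- function(x) x@windows

#' @describeIn PeptideSet-class deduplicated peptide strings (predictor
#'   submission view), in order of first occurrence.
#' @export
peptides <- function(x) unique(x@windows$peptide)

#' @describeIn PeptideSet-class mutation label.
#' @export
mutationId <- function(x) x@mutationId

setMethod("show", "PeptideSet", function(object) {
  cat("PeptideSet", object@mutationId, ":", nrow(object@windows),
      "windows (k", object@kRange[1], "-", object@kRange[2], "),",
      length(unique(object@windows$peptide)), "distinct peptides\n")
})

#' RankTable: percentile ranks for (allele, peptide) pairs
#'
#' Holds predictor output: the percentile rank (eluted-ligand rank, in
#' percent, lower = better predicted presentation) of each peptide for
#' each HLA class I allele.
#'
#' @slot ranks data.frame \code{allele}, \code{peptide},
#'   \code{percent_rank} in (0, 100].
#' @exportClass RankTable
setClass("RankTable", representation(ranks = "data.frame"))

setValidity("RankTable", function(object) {
  r <- object@ranks
  if (!all(c("allele", "peptide", "percent_rank") %in% names(r)))
    return("ranks needs allele, peptide, percent_rank")
  if (nrow(r)) {
    if (any(!is.finite(r$percent_rank)) || any(r$percent_rank <= 0) ||
        any(r$percent_rank > 100))
      return("percent_rank must lie in (0, 100]")
    if (anyDuplicated(r[, c("allele", "peptide")]))
      return("duplicate (allele, peptide) pair")
  }
  TRUE
})

#' Construct a RankTable
#' @param ranks data.frame with columns allele, peptide, percent_rank.
#' @return A \linkS4class{RankTable}.
#' @export
RankTable <- function(ranks) {
  ranks <- as.data.frame(ranks)
  ranks$allele <- parseHlaAllele(ranks$allele)$allele
  ranks$peptide <- as.character(ranks$peptide)
  ranks$percent_rank <- as.numeric(ranks$percent_rank)
  key <- paste(ranks$allele, ranks$peptide, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(ranks$percent_rank, key, function(v) length(unique(v)))
    if (any(agg > 1L))
      stop("conflicting duplicate (allele, peptide) ranks")
    ranks <- ranks[!duplicated(key), ]
  }
  rownames(ranks) <- NULL
  new("RankTable", ranks = ranks)
}

#' @describeIn RankTable-class underlying data.frame.
#' @param x a \code{RankTable}.
#' @export
rankEntries <- function(x) x@ranks

setMethod("show", "RankTable", function(object) {
  cat("RankTable:", nrow(object@ranks), "entries,",
      length(unique(object@ranks$allele)), "alleles,",
      length(unique(object@ranks$peptide)), "peptides\n")
})
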