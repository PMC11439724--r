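#' Read a cohort genotype table
#'
#' Reads the package's genotype interchange format: a UTF-8 TSV with
#' header columns \code{subject_id}, \code{cohort}, \code{group},
#' \code{age}, \code{sex} followed by \code{<LOCUS>_1}/\code{<LOCUS>_2}
#' allele pairs for any subset of the seven HLA loci. Empty cells or
#' \code{"NA"} mean missing. A locus with exactly one missing allele is
#' dropped for that subject with a warning (presentation and divergence
#' scores need genuine pairs; a lone allele would fabricate
#' homozygosity).
#'
#' @param path path to the TSV file.
#' @param name cohort label; defaults to the value of the \code{cohort}
#'   column of the first row, falling back to the file name.
#' @return An \linkS4class{HlaCohort}.
#' @export
readGenotypeTable <- function(path, name = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = c("", "NA"),
                   check.names = FALSE)
  need <- c("subject_id", "cohort", "group", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genotype table misses mandatory columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in genotype table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  badGroup <- !(df$group %in% c("CALR", "JAK2", "CONTROL"))
  if (any(badGroup))
    stop("group values outside {CALR, JAK2, CONTROL}: ",
         paste(unique(df$group[badGroup]), collapse = ", "))
  subjects <- data.frame(subject_id = df$subject_id, cohort = df$cohort,
                         group = df$group,
                         age = suppressWarnings(as.numeric(df$age)),
                         sex = df$sex)
  loci <- intersect(HLA_LOCI, unique(sub("_[12]$", "",
    grep("_[12]$", names(df), value = TRUE))))
  rows <- list()
  for (loc in loci) {
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (!all(c(c1, c2) %in% names(df))) next
    a1 <- df[[c1]]; a2 <- df[[c2]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      warning("dropping locus ", loc, " for subject(s) with one missing ",
              "allele: ", paste(df$subject_id[half], collapse = ", "))
    keep <- !is.na(a1) & !is.na(a2)
    if (any(keep))
      rows[[loc]] <- data.frame(subject_id = df$subject_id[keep],
                                locus = loc, allele1 = a1[keep],
                                allele2 = a2[keep])
  }
  genotypes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), locus = character(),
               allele1 = character(), allele2 = character())
  if (is.null(name))
    name <- if (nrow(df) && !is.na(df$cohort[1])) df$cohort[1] else
      tools::file_path_sans_ext(basename(path))
  HlaCohort(name, subjects, genotypes)
}

#' Write a cohort genotype table
#'
#' Emits the same TSV dialect \code{readGenotypeTable} reads, so that
#' write-then-read round-trips a cohort.
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(x, path) {
  stopifnot(is(x, "HlaCohort"))
  s <- subjectTable(x)
  out <- s
  g <- genotypeTable(x)
  for (loc in intersect(HLA_LOCI, unique(g$locus))) {
    gl <- g[g$locus == loc, ]
    i <- match(s$subject_id, gl$subject_id)
    out[[paste0(loc, "_1")]] <- gl$allele1[i]
    out[[paste0(loc, "_2")]] <- gl$allele2[i]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read IMGT-style allele protein sequences
#'
#' Loads a protein FASTA whose record headers contain an HLA allele name
#' (IMGT headers such as \code{"HLA:HLA00001 A*01:01:01:01 365 bp"} are
#' accepted, as is a bare allele name). Per two-field allele, the first
#' full-length sequence encountered is kept (reference-allele
#' convention). An optional per-locus residue range extracts the
#' peptide-binding domain; sequences with non-standard characters are
#' rejected with a warning, and a per-locus equal-length check runs after
#' extraction.
#'
#' @param path FASTA file path.
#' @param domainRanges optional named list \code{locus -> c(start, end)}
#'   (1-based, inclusive) selecting the binding-groove segment.
#' @return An \linkS4class{AlleleSequenceDB}.
#' @export
readImgtProteinFasta <- function(path, domainRanges = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("empty FASTA: ", path)
    return(new("AlleleSequenceDB", sequences = Biostrings::AAStringSet(),
               locus = character()))
  }
  hdr <- names(aa)
  tok <- regmatches(hdr, regexpr(
    "(HLA-)?(A|B|C|DPB1|DQA1|DQB1|DRB1)\\*[0-9]+(:[0-9]+)+[NLSQCA]?", hdr))
  found <- lengths(regmatches(hdr, gregexpr(
    "(HLA-)?(A|B|C|DPB1|DQA1|DQB1|DRB1)\\*[0-9]+(:[0-9]+)+[NLSQCA]?", hdr))) > 0
  if (any(!found))
    stop("FASTA header without parseable allele name: ",
         paste(head(hdr[!found], 3L), collapse = "; "))
  parsed <- parseHlaAllele(tok)
  seqs <- as.character(aa)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  if (any(!ok)) {
    warning("rejecting ", sum(!ok), " record(s) with gap or non-standard ",
            "residues: ", paste(head(parsed$allele[!ok], 5L), collapse = ", "))
    seqs <- seqs[ok]; parsed <- parsed[ok, ]
  }
  keep <- !duplicated(parsed$allele)   # first full-length record wins
  seqs <- seqs[keep]; parsed <- parsed[keep, ]
  if (!is.null(domainRanges)) {
    for (loc in intersect(names(domainRanges), parsed$locus)) {
      rng <- domainRanges[[loc]]
      i <- parsed$locus == loc
      short <- nchar(seqs[i]) < rng[2]
      if (any(short))
        stop("sequence(s) shorter than domain range at locus ", loc, ": ",
             paste(parsed$allele[i][short], collapse = ", "))
      seqs[i] <- substring(seqs[i], rng[1], rng[2])
    }
  }
  for (loc in unique(parsed$locus)) {
    w <- nchar(seqs[parsed$locus == loc])
    if (length(unique(w)) > 1L)
      stop("unequal extracted lengths at locus ", loc, ": ",
           paste(parsed$allele[parsed$locus == loc], collapse = ", "))
  }
  names(seqs) <- parsed$allele
  new("AlleleSequenceDB", sequences = Biostrings::AAStringSet(seqs),
      locus = parsed$locus)
}

#' Per-locus allele counts and frequencies
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param locus locus to tabulate.
#' @return data.frame \code{allele}, \code{carriers} (subjects with at
#'   least one copy), \code{count} (allele copies), \code{frequency}
#'   (copies / 2n over subjects typed at the locus). Frequencies sum to 1.
#' @export
alleleCounts <- function(x, locus) {
  g <- genotypesAt(x, locus)
  if (nrow(g) == 0L) stop("no subject typed at locus ", locus)
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  count <- vapply(alleles, function(a)
    sum(g$allele1 == a) + sum(g$allele2 == a), 0L)
  carriers <- vapply(alleles, function(a)
    sum(g$allele1 == a | g$allele2 == a), 0L)
  data.frame(allele = alleles, carriers = carriers, count = count,
             frequency = count / (2 * nrow(g)), row.names = NULL)
}
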