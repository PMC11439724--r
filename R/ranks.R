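#' Read a percentile-rank table
#'
#' Two dialects are supported. \code{"simple_tsv"} is the package's
#' canonical interchange: a TSV with columns \code{allele},
#' \code{peptide}, \code{percent_rank}. \code{"netmhcpan_tab"} parses the
#' predictor's multi-allele tab export: comment lines (\code{#}) are
#' skipped, the first remaining line carries the allele names positioned
#' over their column blocks, the second is the per-column header in
#' which each allele block ends with an \code{EL_Rank}-style column; the
#' k-th rank column is attributed to the k-th allele of the header line.
#'
#' Duplicate (allele, peptide) pairs with equal ranks collapse; with
#' conflicting ranks the read fails.
#'
#' @param path input file.
#' @param dialect \code{"simple_tsv"} (default) or
#'   \code{"netmhcpan_tab"}.
#' @return A \linkS4class{RankTable}.
#' @export
readRankTable <- function(path, dialect = c("simple_tsv", "netmhcpan_tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple_tsv") {
    df <- read.delim(path, sep = "\t", header = TRUE,
                     colClasses = "character")
    need <- c("allele", "peptide", "percent_rank")
    if (!all(need %in% names(df)))
      stop("rank table needs columns: ", paste(need, collapse = ", "))
    pr <- suppressWarnings(as.numeric(df$percent_rank))
    if (anyNA(pr)) stop("unparseable percent_rank value(s)")
    if (any(pr <= 0)) stop("percent_rank must be strictly positive")
    return(RankTable(data.frame(allele = df$allele, peptide = df$peptide,
                                percent_rank = pr)))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 3L) stop("truncated predictor export")
  f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  alleles <- f1[nzchar(f1)]
  f2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  rankCols <- grep("^(EL_)?%?Rank(_EL)?$", f2)
  pepCol <- which(f2 == "Peptide")[1]
  if (is.na(pepCol) || length(rankCols) == 0L)
    stop("predictor export header lacks Peptide / rank columns")
  if (length(rankCols) < length(alleles))
    stop("fewer rank columns than allele names in predictor export")
  rankCols <- rankCols[seq_along(alleles)]
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  out <- do.call(rbind, lapply(rows, function(f) {
    pr <- suppressWarnings(as.numeric(f[rankCols]))
    if (anyNA(pr)) stop("unparseable rank in predictor export")
    data.frame(allele = alleles, peptide = f[pepCol], percent_rank = pr)
  }))
  if (any(out$percent_rank <= 0))
    stop("percent_rank must be strictly positive")
  RankTable(out)
}

#' Write a rank table in the canonical TSV dialect
#'
#' @param x a \linkS4class{RankTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRankTable <- function(x, path) {
  stopifnot(is(x, "RankTable"))
  write.table(rankEntries(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# 32-bit FNV-1a over the bytes of a string vector; pure arithmetic so the
# result is bit-identical across platforms and R versions.
.fnv1a <- function(strings) {
  h <- rep(2166136261, length(strings))
  maxn <- max(nchar(strings), 0L)
  for (i in seq_len(maxn)) {
    ch <- substr(strings, i, i)
    live <- nchar(strings) >= i
    b <- ifelse(live, utf8ToInt(paste(ifelse(live, ch, "a"), collapse = ""))[
      seq_along(strings)], 0)
    # xor then multiply by the FNV prime mod 2^32, in split 16-bit halves
    hx <- bitwXor(as.integer(h %% 65536), as.integer(b %% 256))
    hh <- floor(h / 65536)
    hNew <- (hh * 65536 + hx) %% 4294967296
    lo <- hNew %% 65536
    hi <- floor(hNew / 65536)
    prod <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    h <- ifelse(live, prod, h)
  }
  h
}

#' Deterministic mock percentile-rank predictor
#'
#' Stand-in for the external binding predictor used in tests and
#' synthetic studies: each (allele, peptide) pair receives a percent
#' rank in (0, 100] derived from an integer hash of
#' \code{"allele|peptide|seed"}, so identical inputs and seed reproduce
#' identical tables on any platform, with no R RNG involvement.
#' Specific pairs can be planted to exact values.
#'
#' @param alleles character vector of allele names.
#' @param peptideStrings character vector of peptides (deduplicated
#'   internally).
#' @param seed integer seed folded into the hash.
#' @param planted optional data.frame \code{allele}, \code{peptide},
#'   \code{percent_rank} overriding the hashed values.
#' @return A \linkS4class{RankTable} with one entry per (allele,
#'   peptide) pair.
#' @export
mockRankPredictor <- function(alleles, peptideStrings, seed,
                              planted = NULL) {
  alleles <- parseHlaAllele(alleles)$allele
  peptideStrings <- unique(as.character(peptideStrings))
  grid <- expand.grid(allele = alleles, peptide = peptideStrings,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$allele, grid$peptide, as.integer(seed), sep = "|")
  h <- .fnv1a(key)
  grid$percent_rank <- (h + 1) / 4294967296 * 100
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (any(planted$percent_rank <= 0 | planted$percent_rank > 100))
      stop("planted ranks must lie in (0, 100]")
    pa <- parseHlaAllele(planted$allele)$allele
    i <- match(paste(pa, planted$peptide),
               paste(grid$allele, grid$peptide))
    if (anyNA(i)) stop("planted pair not in the allele x peptide grid")
    grid$percent_rank[i] <- planted$percent_rank
  }
  RankTable(grid)
}

#' Best rank of an allele for a mutation's peptide set
#'
#' The best rank (BR) is the minimum percentile rank over the
#' deduplicated peptide strings of the mutation's enumeration: the
#' allele's single best predicted presentation of any mutant window.
#'
#' @param table a \linkS4class{RankTable}.
#' @param allele one allele name.
#' @param pset the mutation's \linkS4class{PeptideSet}.
#' @param maxMissing maximum tolerated fraction of the peptide set
#'   without a prediction for this allele (default 0: fail loudly).
#' @param missingRank if non-NULL, missing peptides are imputed at this
#'   rank instead of counting against \code{maxMissing} (robustness
#'   experiments only).
#' @return One-row data.frame \code{allele}, \code{mutation_id},
#'   \code{br}.
#' @export
bestRank <- function(table, allele, pset, maxMissing = 0,
                     missingRank = NULL) {
  stopifnot(is(table, "RankTable"), is(pset, "PeptideSet"))
  allele <- parseHlaAllele(allele)$allele
  peps <- peptides(pset)
  r <- rankEntries(table)
  r <- r[r$allele == allele, ]
  if (nrow(r) == 0L) stop("no predictions for allele ", allele)
  pr <- r$percent_rank[match(peps, r$peptide)]
  if (anyNA(pr)) {
    if (!is.null(missingRank)) {
      pr[is.na(pr)] <- missingRank
    } else if (mean(is.na(pr)) > maxMissing) {
      stop(sprintf("%.0f%% of %s peptides lack predictions for %s",
                   100 * mean(is.na(pr)), mutationId(pset), allele))
    }
  }
  data.frame(allele = allele, mutation_id = mutationId(pset),
             br = min(pr, na.rm = TRUE))
}

#' Best ranks for many alleles at once
#'
#' @inheritParams bestRank
#' @param alleles character vector of allele names.
#' @return data.frame with one row per allele (columns as
#'   \code{\link{bestRank}}).
#' @export
alleleBestRanks <- function(table, alleles, pset, maxMissing = 0,
                            missingRank = NULL) {
  do.call(rbind, lapply(unique(alleles), function(a)
    bestRank(table, a, pset, maxMissing, missingRank)))
}

#' Harmonic-mean presentation score from best ranks
#'
#' The patient harmonic-mean best rank (PHBR) summarises a class I
#' genotype's ability to present a mutation's neoantigens: the harmonic
#' mean of the six allele best ranks (both alleles of A, B and C, with a
#' homozygous allele's BR counted twice). A low PHBR means at least one
#' allele presents some mutant peptide well.
#'
#' @param brs numeric vector of best ranks, one per allele copy
#'   (homozygous alleles repeated).
#' @return \code{length(brs) / sum(1 / brs)}.
#' @export
harmonicMeanBR <- function(brs) {
  brs <- as.numeric(brs)
  if (length(brs) == 0L || any(!is.finite(brs)) || any(brs <= 0))
    stop("best ranks must be positive and finite")
  length(brs) / sum(1 / brs)
}

#' PHBR of one subject for one mutation
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param subjectId subject identifier.
#' @param brTable data.frame from \code{\link{alleleBestRanks}} (or any
#'   with columns \code{allele}, \code{br}) covering both alleles of all
#'   three class I loci of the subject.
#' @param mutation_id label for the output row.
#' @return One-row data.frame \code{subject_id}, \code{mutation_id},
#'   \code{phbr}, \code{n_alleles_used}.
#' @export
subjectPhbr <- function(x, subjectId, brTable, mutation_id) {
  g <- genotypeTable(x)
  g <- g[g$subject_id == subjectId & g$locus %in% HLA_CLASS_I, ]
  missingLoci <- setdiff(HLA_CLASS_I, g$locus)
  if (length(missingLoci))
    stop("subject ", subjectId, " lacks class I locus/loci: ",
         paste(missingLoci, collapse = ", "))
  alleles <- as.character(rbind(g$allele1, g$allele2))  # 6 copies
  br <- brTable$br[match(alleles, brTable$allele)]
  if (anyNA(br))
    stop("no best rank for allele(s): ",
         paste(unique(alleles[is.na(br)]), collapse = ", "))
  data.frame(subject_id = subjectId, mutation_id = mutation_id,
             phbr = harmonicMeanBR(br), n_alleles_used = length(br))
}

#' Annotate best ranks as strong/weak/non-binders
#'
#' Applies the predictor's standard thresholds: strong binder (SB) at a
#' percent rank of at most 0.5, weak binder (WB) above that up to 2, and
#' non-binder (NB) beyond. Both boundaries are inclusive on the
#' lower-category side.
#'
#' @param br numeric vector of (best) ranks, all positive.
#' @param tSB,tWB thresholds in percent-rank units.
#' @return Factor with levels SB, WB, NB.
#' @export
categorizeBinder <- function(br, tSB = 0.5, tWB = 2.0) {
  br <- as.numeric(br)
  if (any(!is.finite(br)) || any(br <= 0))
    stop("ranks must be positive and finite")
  factor(ifelse(br <= tSB, "SB", ifelse(br <= tWB, "WB", "NB")),
         levels = c("SB", "WB", "NB"))
}

#' PHBR table for a whole cohort
#'
#' Computes per-subject PHBRs for each mutation. Subjects with an
#' incomplete class I genotype are skipped and listed in the
#' \code{"skipped"} attribute rather than silently imputed.
#'
#' @param x an \linkS4class{HlaCohort}.
#' @param rankTables named list of \linkS4class{RankTable}s, one per
#'   mutation id.
#' @param psets named list of \linkS4class{PeptideSet}s with matching
#'   names.
#' @param maxMissing,missingRank passed to \code{\link{bestRank}}.
#' @return data.frame \code{subject_id}, \code{mutation_id},
#'   \code{phbr}, \code{n_alleles_used}; attribute \code{skipped} is a
#'   data.frame \code{subject_id}, \code{reason}.
#' @export
cohortPhbrTable <- function(x, rankTables, psets, maxMissing = 0,
                            missingRank = NULL) {
  stopifnot(identical(sort(names(rankTables)), sort(names(psets))))
  g <- genotypeTable(x)
  gI <- g[g$locus %in% HLA_CLASS_I, ]
  complete <- names(which(tapply(gI$locus, gI$subject_id,
                                 function(l) length(unique(l)) == 3L)))
  ids <- subjectTable(x)$subject_id
  notComplete <- setdiff(ids, complete)
  skipped <- data.frame(subject_id = notComplete,
                        reason = rep("incomplete class I genotype",
                                     length(notComplete)))
  rows <- list()
  for (m in names(psets)) {
    alleles <- sort(unique(c(gI$allele1, gI$allele2)))
    brTab <- alleleBestRanks(rankTables[[m]], alleles, psets[[m]],
                             maxMissing, missingRank)
    for (sid in intersect(ids, complete))
      rows[[length(rows) + 1L]] <- subjectPhbr(x, sid, brTab, m)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), mutation_id = character(),
               phbr = numeric(), n_alleles_used = integer())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
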