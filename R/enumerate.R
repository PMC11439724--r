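#' Built-in mutation contexts
#'
#' \code{calrNeoContext()} returns the 44-residue neomorphic C-terminal
#' amino-acid sequence shared by the recurrent CALR exon 9 frameshift
#' mutations; every 8-11-mer window of it is a candidate neoantigen
#' (142 windows). \code{jak2V617FContext()} returns the canonical JAK2
#' pseudokinase segment spanning residues 607-627 with the V617F
#' substitution applied; the mutated residue sits at local position 11
#' with ten flanking residues on each side, so 8-11-mer windows
#' containing it number 38.
#'
#' @return A list with elements \code{mutation_id}, \code{mode}
#'   (\code{"NEO_TERMINUS"} or \code{"POINT_SUBSTITUTION"}),
#'   \code{sequence}, and for point substitutions \code{mutated_position}
#'   (1-based, into \code{sequence}).
#' @examples
#' windowCount(enumerateNeoTerminus(calrNeoContext()))   # 142
#' windowCount(enumeratePointMutation(jak2V617FContext())) # 38
#' @export
calrNeoContext <- function() {
  mutationContext("CALRmut", "NEO_TERMINUS",
                  "RRMMRTKMRMRRMRRTRRKMRRKMSPARPRTSCREACLQGWTEA")
}

#' @rdname calrNeoContext
#' @export
jak2V617FContext <- function() {
  mutationContext("JAK2V617F", "POINT_SUBSTITUTION",
                  "KHLVLNYGVCFCGDENILVQE", mutated_position = 11L)
}

#' Describe a mutation for peptide enumeration
#'
#' @param mutation_id label carried into downstream tables.
#' @param mode \code{"NEO_TERMINUS"} (a novel protein segment, every
#'   window is mutant) or \code{"POINT_SUBSTITUTION"} (only windows
#'   covering the substituted residue are mutant).
#' @param sequence amino-acid string; for point substitutions it must
#'   already carry the mutant residue.
#' @param mutated_position 1-based index of the substituted residue
#'   (POINT_SUBSTITUTION only).
#' @return A mutation-context list (see \code{\link{calrNeoContext}}).
#' @export
mutationContext <- function(mutation_id, mode, sequence,
                            mutated_position = NA_integer_) {
  mode <- match.arg(mode, c("NEO_TERMINUS", "POINT_SUBSTITUTION"))
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence))
    stop("sequence must use the 20 standard residues")
  if (nchar(sequence) < 8L) stop("sequence must be at least 8 residues")
  if (mode == "POINT_SUBSTITUTION") {
    mutated_position <- as.integer(mutated_position)
    if (is.na(mutated_position) || mutated_position < 1L ||
        mutated_position > nchar(sequence))
      stop("mutated_position must index into the sequence")
  }
  structure(list(mutation_id = as.character(mutation_id), mode = mode,
                 sequence = sequence, mutated_position = mutated_position),
            class = "MutationContext")
}

.windowsOf <- function(sequence, kMin, kMax) {
  L <- nchar(sequence)
  out <- list()
  for (k in seq.int(kMin, kMax)) {
    if (k > L) next
    start <- seq_len(L - k + 1L)
    out[[length(out) + 1L]] <- data.frame(start = start, length = k)
  }
  w <- do.call(rbind, out)
  w <- w[order(w$start, w$length), , drop = FALSE]
  w$peptide <- substring(sequence, w$start, w$start + w$length - 1L)
  rownames(w) <- NULL
  w
}

#' Enumerate neoantigen windows from a neo-terminus
#'
#' Produces every substring of each length in \code{[kMin, kMax]} from a
#' novel protein segment (all windows are mutant by construction). For
#' the built-in CALR neomorphic C-terminus the 8-11-mer count is 142.
#'
#' @param context a NEO_TERMINUS mutation context.
#' @param kMin,kMax inclusive window-length bounds (defaults 8 and 11,
#'   the class I lengths).
#' @return A \linkS4class{PeptideSet}; counts are positional (windows),
#'   with deduplicated strings available via \code{\link{peptides}}.
#' @export
enumerateNeoTerminus <- function(context, kMin = 8L, kMax = 11L) {
  stopifnot(inherits(context, "MutationContext"),
            context$mode == "NEO_TERMINUS")
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  L <- nchar(context$sequence)
  if (kMin > kMax) stop("kMin must not exceed kMax")
  if (kMin > L) stop("kMin exceeds the context length")
  w <- .windowsOf(context$sequence, kMin, min(kMax, L))
  new("PeptideSet", mutationId = context$mutation_id,
      context = context$sequence, windows = w,
      kRange = c(kMin, kMax))
}

#' Enumerate neoantigen windows around a point substitution
#'
#' Produces every substring of each length in \code{[kMin, kMax]} that
#' contains the mutated residue; near the sequence ends the set is
#' clipped to valid windows. With at least \code{kMax - 1} residues of
#' flank on both sides the count is \code{sum(kMin:kMax)} (38 for the
#' default 8-11).
#'
#' @param context a POINT_SUBSTITUTION mutation context.
#' @param kMin,kMax inclusive window-length bounds.
#' @return A \linkS4class{PeptideSet}.
#' @export
enumeratePointMutation <- function(context, kMin = 8L, kMax = 11L) {
  stopifnot(inherits(context, "MutationContext"),
            context$mode == "POINT_SUBSTITUTION")
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (kMin > kMax) stop("kMin must not exceed kMax")
  L <- nchar(context$sequence)
  if (kMin > L) stop("kMin exceeds the context length")
  pos <- context$mutated_position
  w <- .windowsOf(context$sequence, kMin, min(kMax, L))
  covers <- w$start <= pos & pos <= w$start + w$length - 1L
  w <- w[covers, , drop = FALSE]
  rownames(w) <- NULL
  new("PeptideSet", mutationId = context$mutation_id,
      context = context$sequence, windows = w,
      kRange = c(kMin, kMax))
}

#' Enumerate 15-mer windows for class II prediction input
#'
#' Class II predictors take 15-mers. For a neo-terminus every 15-mer
#' window is produced; for a point substitution only the 15-mers covering
#' the mutated residue.
#'
#' @param context a mutation context.
#' @param k window length (default 15).
#' @return A \linkS4class{PeptideSet}.
#' @export
enumerateClassII <- function(context, k = 15L) {
  stopifnot(inherits(context, "MutationContext"))
  k <- as.integer(k)
  if (nchar(context$sequence) < k)
    stop("context shorter than ", k, " residues")
  if (context$mode == "NEO_TERMINUS")
    enumerateNeoTerminus(context, k, k)
  else
    enumeratePointMutation(context, k, k)
}

#' Write enumerated peptides to a file
#'
#' @param pset a \linkS4class{PeptideSet}.
#' @param path output path.
#' @param format \code{"fasta"} writes one record per positional window,
#'   named \code{"<mutation_id>_<start>_<length>"}; \code{"list"} writes
#'   one deduplicated peptide string per line (the predictor-submission
#'   view).
#' @return \code{path}, invisibly.
#' @export
writePeptides <- function(pset, path, format = c("fasta", "list")) {
  format <- match.arg(format)
  w <- windowTable(pset)
  if (format == "fasta") {
    recs <- Biostrings::AAStringSet(w$peptide)
    names(recs) <- sprintf("%s_%d_%d", mutationId(pset), w$start, w$length)
    Biostrings::writeXStringSet(recs, path)
  } else {
    writeLines(unique(w$peptide), path)
  }
  invisible(path)
}
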