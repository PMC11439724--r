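#' HLA loci covered by the package
#'
#' Class I loci (A, B, C) present peptides to CD8+ T cells; class II loci
#' (DPB1, DQA1, DQB1, DRB1) to CD4+ T cells.
#'
#' @export
HLA_LOCI <- c("A", "B", "C", "DPB1", "DQA1", "DQB1", "DRB1")

#' @rdname HLA_LOCI
#' @export
HLA_CLASS_I <- c("A", "B", "C")

#' @rdname HLA_LOCI
#' @export
HLA_CLASS_II <- c("DPB1", "DQA1", "DQB1", "DRB1")

#' Parse HLA allele names to two-field resolution
#'
#' Accepts standard HLA nomenclature such as \code{"C*06:02"},
#' \code{"HLA-A*02:01:01:02"} or \code{"B*35:01N"}. The optional
#' \code{"HLA-"} prefix is removed, resolution beyond two fields is
#' truncated, and expression-suffix letters (N, L, S, Q, C, A) are stripped
#' with a flag. All analyses in this package operate at two-field (allele
#' group + protein) resolution.
#'
#' @param text character vector of allele names.
#' @return A data.frame with one row per input: \code{locus},
#'   \code{field1}, \code{field2} (integers), \code{suffix_stripped}
#'   (logical) and \code{allele}, the canonical two-field rendering
#'   (zero-padded to at least two digits per field).
#' @examples
#' parseHlaAllele(c("C*06:02", "HLA-A*02:01:01:02"))
#' @export
parseHlaAllele <- function(text) {
  if (length(text) == 0L) {
    return(data.frame(locus = character(), field1 = integer(),
                      field2 = integer(), suffix_stripped = logical(),
                      allele = character()))
  }
  text <- as.character(text)
  if (anyNA(text) || any(!nzchar(text)))
    stop("allele strings must be non-empty and non-NA")
  x <- sub("^HLA-", "", trimws(text))
  star <- regexpr("*", x, fixed = TRUE)
  if (any(star < 0L))
    stop("malformed HLA allele (missing '*'): ",
         paste(text[star < 0L], collapse = ", "))
  locus <- substr(x, 1L, star - 1L)
  bad <- !(locus %in% HLA_LOCI)
  if (any(bad))
    stop("unknown HLA locus in: ", paste(text[bad], collapse = ", "))
  rest <- substr(x, star + 1L, nchar(x))
  suffix_stripped <- grepl("[NLSQCA]$", rest)
  rest <- sub("[NLSQCA]$", "", rest)
  fields <- strsplit(rest, ":", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("malformed HLA allele (need at least two ':'-separated fields): ",
         paste(text[nf < 2L], collapse = ", "))
  f1c <- vapply(fields, `[`, "", 1L)
  f2c <- vapply(fields, `[`, "", 2L)
  okNum <- grepl("^[0-9]+$", f1c) & grepl("^[0-9]+$", f2c)
  if (any(!okNum))
    stop("non-numeric allele fields in: ",
         paste(text[!okNum], collapse = ", "))
  field1 <- as.integer(f1c)
  field2 <- as.integer(f2c)
  data.frame(locus = locus, field1 = field1, field2 = field2,
             suffix_stripped = suffix_stripped,
             allele = formatHlaAllele(locus, field1, field2))
}

#' Render the canonical two-field allele name
#'
#' @param locus locus name (one of \code{HLA_LOCI}).
#' @param field1,field2 allele-group and protein fields, non-negative
#'   integers.
#' @return Character vector such as \code{"C*06:02"}; fields are
#'   zero-padded to a minimum of two digits.
#' @export
formatHlaAllele <- function(locus, field1, field2) {
  stopifnot(all(locus %in% HLA_LOCI), all(field1 >= 0), all(field2 >= 0))
  sprintf("%s*%s:%s", locus,
          formatC(as.integer(field1), width = 2, flag = "0"),
          formatC(as.integer(field2), width = 2, flag = "0"))
}

#' HLA class of a locus or allele name
#'
#' @param x locus names or full allele names (anything `parseHlaAllele`
#'   accepts).
#' @return Character vector, \code{"I"} or \code{"II"}.
#' @export
hlaClass <- function(x) {
  locus <- ifelse(grepl("*", x, fixed = TRUE), parseHlaAllele(x)$locus, x)
  if (any(!(locus %in% HLA_LOCI))) stop("unknown HLA locus")
  ifelse(locus %in% HLA_CLASS_I, "I", "II")
}

#' Locus of canonical allele names
#' @param allele canonical allele strings.
#' @return Character vector of loci.
#' @export
hlaLocusOf <- function(allele) parseHlaAllele(allele)$locus
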