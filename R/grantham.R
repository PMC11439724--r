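.granthamEnv <- new.env(parent = emptyenv())

#' The Grantham amino-acid distance matrix
#'
#' Returns the 20x20 integer-rounded Grantham (1974) distance matrix
#' shipped with the package as a plain-text file. The distance combines
#' differences in side-chain composition, polarity and molecular volume;
#' it is symmetric with a zero diagonal, and the file header declares
#' the rounding tolerance (1) within which every entry agrees with the
#' closed-form distance of \code{\link{granthamDistanceFormula}}.
#'
#' @return Numeric 20x20 matrix with residue dimnames.
#' @export
granthamMatrix <- function() {
  if (is.null(.granthamEnv$matrix)) {
    path <- system.file("extdata", "grantham_distance.tsv",
                        package = "hlaImmunoedit", mustWork = TRUE)
    df <- read.delim(path, sep = "\t", comment.char = "#",
                     header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$aa
    storage.mode(m) <- "double"
    stopifnot(isSymmetric(m), all(diag(m) == 0))
    .granthamEnv$matrix <- m
  }
  .granthamEnv$matrix
}

#' Grantham's residue property values and formula constants
#'
#' Side-chain composition (\code{c}), polarity (\code{p}) and molecular
#' volume (\code{v}) per residue, with the weighting constants of the
#' original distance formula, kept as the independent oracle against
#' which the shipped matrix is validated.
#'
#' @return A list with elements \code{properties} (data.frame \code{aa},
#'   \code{c}, \code{p}, \code{v}) and \code{constants} (\code{alpha},
#'   \code{beta}, \code{gamma}, \code{rho}).
#' @export
granthamProperties <- function() {
  properties <- data.frame(
    aa = c("S","R","L","P","T","A","V","G","I","F",
           "Y","C","H","Q","N","K","D","E","M","W"),
    c  = c(1.42,0.65,0,0.39,0.71,0,0,0.74,0,0,
           0.20,2.75,0.58,0.89,1.33,0.33,1.38,0.92,0,0.13),
    p  = c(9.2,10.5,4.9,8.0,8.6,8.1,5.9,9.0,5.2,5.2,
           6.2,5.5,10.4,10.5,11.6,11.3,13.0,12.3,5.7,5.4),
    v  = c(32,124,111,32.5,61,31,84,3,111,132,
           136,55,96,85,56,119,54,83,105,170))
  list(properties = properties,
       constants = list(alpha = 1.833, beta = 0.1018, gamma = 0.000399,
                        rho = 50.723))
}

#' Grantham distance between residues (table lookup)
#'
#' @param a,b single-letter residue vectors (recycled to a common
#'   length).
#' @return Numeric vector of distances; \code{d(x, x) = 0}.
#' @export
granthamDistance <- function(a, b) {
  m <- granthamMatrix()
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (any(!(a %in% rownames(m))) || any(!(b %in% rownames(m))))
    stop("non-standard residue passed to granthamDistance")
  m[cbind(match(a, rownames(m)), match(b, colnames(m)))]
}

#' Grantham distance from the closed-form formula
#'
#' Computes \code{rho * sqrt(alpha*(c_a-c_b)^2 + beta*(p_a-p_b)^2 +
#' gamma*(v_a-v_b)^2)} from the residue property values, without
#' rounding. Used to validate the shipped integer matrix.
#'
#' @param a,b single-letter residue vectors.
#' @return Numeric vector of unrounded distances.
#' @export
granthamDistanceFormula <- function(a, b) {
  gp <- granthamProperties()
  pr <- gp$properties; k <- gp$constants
  ia <- match(toupper(a), pr$aa); ib <- match(toupper(b), pr$aa)
  if (anyNA(ia) || anyNA(ib))
    stop("non-standard residue passed to granthamDistanceFormula")
  k$rho * sqrt(k$alpha * (pr$c[ia] - pr$c[ib])^2 +
               k$beta  * (pr$p[ia] - pr$p[ib])^2 +
               k$gamma * (pr$v[ia] - pr$v[ib])^2)
}
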