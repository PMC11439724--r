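# Conditional distribution of the heterozygote count given the minor
# allele count nA and sample size n, computed by the stable ratio
# recurrence P(nAB + 2) / P(nAB) = 4 nAA nBB / ((nAB + 2)(nAB + 1)).
.hweHetDistribution <- function(n, nA) {
  nB <- 2L * n - nA
  m <- min(nA, nB)
  hets <- seq.int(m %% 2L, m, by = 2L)
  if (length(hets) == 1L)
    return(list(het = hets, prob = 1))
  logp <- numeric(length(hets))
  for (i in seq_len(length(hets) - 1L)) {
    nAB <- hets[i]
    nAA <- (nA - nAB) / 2
    nBB <- (nB - nAB) / 2
    logp[i + 1L] <- logp[i] + log(4 * nAA * nBB) -
      log((nAB + 2) * (nAB + 1))
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  list(het = hets, prob = p / sum(p))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic marker (here: one HLA allele
#' against all other alleles of its locus pooled). All heterozygote
#' counts consistent with the observed allele counts are enumerated
#' under the conditional distribution given allele counts; the p-value
#' is the total probability of configurations no more probable than the
#' observed one. Deviation from equilibrium flags genotyping or sampling
#' artifacts and gates the association analysis.
#'
#' @param nAA,nAB,nBB genotype counts: homozygous for the allele,
#'   heterozygous carriers, all other genotypes.
#' @return p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  nAA <- as.integer(nAA); nAB <- as.integer(nAB); nBB <- as.integer(nBB)
  if (any(c(nAA, nAB, nBB) < 0L)) stop("genotype counts must be non-negative")
  n <- nAA + nAB + nBB
  if (n < 1L) stop("need at least one genotype")
  nA <- 2L * nAA + nAB
  d <- .hweHetDistribution(n, min(nA, 2L * n - nA))
  pObs <- d$prob[match(nAB, d$het)]
  sum(d$prob[d$prob <= pObs * (1 + 1e-9)])
}
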