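# Independent oracles used across the suite. Everything here is written
# against first principles (brute force, closed forms, direct
# enumeration) and never calls the code path it checks.

# All substrings of s with lengths in [kMin, kMax]; plain double loop.
bruteForceWindows <- function(s, kMin, kMax, mustCover = NULL) {
  out <- data.frame(start = integer(), length = integer(),
                    peptide = character())
  for (k in kMin:kMax) {
    if (k > nchar(s)) next
    for (st in 1:(nchar(s) - k + 1)) {
      if (!is.null(mustCover) &&
          !(st <= mustCover && mustCover <= st + k - 1)) next
      out <- rbind(out, data.frame(start = st, length = k,
                                   peptide = substr(s, st, st + k - 1)))
    }
  }
  out[order(out$start, out$length), ]
}

# Exact HWE configuration probabilities straight from log-factorials:
# P(nAB | n, nA) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! nB! / (2n)!
hweOracleProbs <- function(n, nA) {
  nB <- 2 * n - nA
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  lp <- vapply(hets, function(nAB) {
    nAA <- (nA - nAB) / 2
    nBB <- (nB - nAB) / 2
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(nAB + 1) - lgamma(nBB + 1) +
      nAB * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(lp - max(lp))
  data.frame(het = hets, prob = p / sum(p))
}

hweOracleP <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  d <- hweOracleProbs(n, min(2 * nAA + nAB, 2 * nBB + nAB))
  pObs <- d$prob[d$het == nAB]
  sum(d$prob[d$prob <= pObs * (1 + 1e-9)])
}

# Multinomial log-likelihood of two-locus unphased genotypes under
# haplotype frequencies f (named by "a-b"); independent enumeration of
# the at most two consistent diplotypes per subject.
twoLocusLogLik <- function(genos, f) {
  ll <- 0
  for (i in seq_len(nrow(genos))) {
    a1 <- genos$a1[i]; a2 <- genos$a2[i]
    b1 <- genos$b1[i]; b2 <- genos$b2[i]
    dips <- unique(list(
      sort(c(paste(a1, b1, sep = "-"), paste(a2, b2, sep = "-"))),
      sort(c(paste(a1, b2, sep = "-"), paste(a2, b1, sep = "-")))))
    p <- sum(vapply(dips, function(d) {
      f1 <- f[d[1]]; f2 <- f[d[2]]
      if (is.na(f1) || is.na(f2)) return(0)
      unname(f1 * f2 * if (d[1] == d[2]) 1 else 2)
    }, 0))
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

# Dense grid search over the simplex with iterative refinement: global
# scan at a coarse step, then repeated zoom on the incumbent maximiser.
gridSearchHaploFreqs <- function(genos, haps, step0 = 0.02) {
  H <- length(haps)
  evalPoint <- function(f) {
    names(f) <- haps
    twoLocusLogLik(genos, f)
  }
  gridAround <- function(center, halfWidth, step) {
    ranges <- lapply(seq_len(H - 1), function(j)
      seq(max(0, center[j] - halfWidth), min(1, center[j] + halfWidth),
          by = step))
    pts <- as.matrix(expand.grid(ranges))
    last <- 1 - rowSums(pts)
    ok <- last >= -1e-12
    cbind(pts[ok, , drop = FALSE], pmax(0, last[ok]))
  }
  best <- rep(1 / H, H); bestLL <- evalPoint(best)
  pts <- gridAround(best, 1, step0)
  for (r in seq_len(nrow(pts))) {
    ll <- evalPoint(pts[r, ])
    if (ll > bestLL) { bestLL <- ll; best <- pts[r, ] }
  }
  hw <- 2 * step0; st <- step0 / 2
  while (st > 2e-6) {
    pts <- gridAround(best, hw, st)
    for (r in seq_len(nrow(pts))) {
      ll <- evalPoint(pts[r, ])
      if (ll > bestLL) { bestLL <- ll; best <- pts[r, ] }
    }
    hw <- hw / 2; st <- st / 2
  }
  setNames(best, haps)
}

# Small deterministic cohort used by several modules: 4 fully typed
# class I subjects plus one subject missing locus C.
makeToyCohort <- function() {
  subjects <- data.frame(
    subject_id = paste0("S", 1:5), cohort = "toy",
    group = c("CALR", "CALR", "CONTROL", "CONTROL", "JAK2"),
    age = c(61, 55, 48, 70, 66), sex = c("M", "F", "F", "M", "M"))
  g <- rbind(
    data.frame(subject_id = "S1", locus = c("A", "B", "C"),
               allele1 = c("A*01:01", "B*08:01", "C*06:02"),
               allele2 = c("A*02:01", "B*35:01", "C*07:01")),
    data.frame(subject_id = "S2", locus = c("A", "B", "C"),
               allele1 = c("A*01:01", "B*08:01", "C*07:01"),
               allele2 = c("A*01:01", "B*35:01", "C*07:01")),
    data.frame(subject_id = "S3", locus = c("A", "B", "C"),
               allele1 = c("A*02:01", "B*35:01", "C*06:02"),
               allele2 = c("A*02:01", "B*35:01", "C*06:02")),
    data.frame(subject_id = "S4", locus = c("A", "B", "C"),
               allele1 = c("A*01:01", "B*08:01", "C*06:02"),
               allele2 = c("A*02:01", "B*08:01", "C*07:01")),
    data.frame(subject_id = "S5", locus = c("A", "B"),
               allele1 = c("A*01:01", "B*35:01"),
               allele2 = c("A*02:01", "B*35:01")))
  HlaCohort("toy", subjects, g)
}

# Two-locus cohort with phase-ambiguous double heterozygotes: nHomA
# subjects homozygous A*01:01/B*07:02, nHomB homozygous
# A*02:01/B*08:01, and nDblHet double heterozygotes.
makeTwoLocusCohort <- function(nHomA = 40L, nHomB = 40L, nDblHet = 20L) {
  ids <- sprintf("T%03d", seq_len(nHomA + nHomB + nDblHet))
  subjects <- data.frame(subject_id = ids, cohort = "toy2",
                         group = "CONTROL", age = 50, sex = "F")
  mk <- function(id, a1, a2, b1, b2) rbind(
    data.frame(subject_id = id, locus = "A", allele1 = a1, allele2 = a2),
    data.frame(subject_id = id, locus = "B", allele1 = b1, allele2 = b2))
  g <- do.call(rbind, c(
    lapply(ids[seq_len(nHomA)], mk, "A*01:01", "A*01:01",
           "B*07:02", "B*07:02"),
    lapply(ids[nHomA + seq_len(nHomB)], mk, "A*02:01", "A*02:01",
           "B*08:01", "B*08:01"),
    lapply(ids[nHomA + nHomB + seq_len(nDblHet)], mk,
           "A*01:01", "A*02:01", "B*07:02", "B*08:01")))
  HlaCohort("toy2", subjects, g)
}

# Rank table covering the toy cohort's class I alleles for a tiny
# peptide set, with hand-chosen ranks.
makeToyRankTable <- function(peps, alleles, base = 5) {
  rows <- expand.grid(allele = alleles, peptide = peps,
                      stringsAsFactors = FALSE)
  rows$percent_rank <- base + seq_len(nrow(rows)) * 0.25
  RankTable(rows)
}
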