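#' Configuration for synthetic study generation
#'
#' Bundles every parameter of the synthetic cohort generator: the
#' per-locus allele frequency spectra (explicit, or Dirichlet-sampled
#' under the run seed), an optional multi-locus haplotype table that
#' induces linkage disequilibrium, an inbreeding coefficient acting as a
#' Hardy-Weinberg violation knob, group sizes, planted per-allele
#' log-odds-ratios with age and sex covariate effects, and the
#' best-rank model (per-mutation log-uniform BR range with an
#' allele-level correlation between the two mutations' BRs).
#'
#' @param seed integer; the single source of randomness for a run.
#' @param loci loci to simulate (default class I).
#' @param alleleFreqs named list locus -> named frequency vector
#'   (sums to 1). If NULL, spectra are drawn per locus from a
#'   symmetric Dirichlet with \code{nAlleles} categories and
#'   concentration \code{concentration}.
#' @param nAlleles,concentration Dirichlet spectrum parameters used when
#'   \code{alleleFreqs} is NULL (defaults 12 and 0.5: a few common and
#'   many rare alleles, the shape of real HLA loci).
#' @param haplotypeFreqs optional list \code{loci}, \code{freq} (named
#'   by haplotype string \code{"A*..:..-B*..:.."}, sums to 1) inducing
#'   LD across those loci; remaining loci are independent.
#' @param inbreeding f in [0, 1): per locus, the second allele copies
#'   the first with probability f (heterozygote deficit; 0 = HWE).
#' @param groupSizes named vector \code{c(CALR=, JAK2=, CONTROL=)}.
#' @param plantedLogOR list with optional elements \code{CALR},
#'   \code{JAK2}: named log-odds-ratios per allele entering that
#'   group's disease model.
#' @param baseline named intercepts of the two disease models (log
#'   odds; defaults give rare-disease prevalences so rejection
#'   sampling is well behaved).
#' @param ageEffect,sexEffect covariate log-odds per year and for male
#'   sex in both disease models.
#' @param ageMean,ageSD age distribution, truncated to [18, 95].
#' @param sexRatio probability of male sex.
#' @param brLogRange named list per mutation of \code{c(lo, hi)} percent
#'   ranks; allele BRs are log-uniform on the range.
#' @param brCorrelation latent correlation rho in [-1, 1] between an
#'   allele's log BRs for the two mutations.
#' @return A \code{SimulationConfig} list.
#' @export
simulationConfig <- function(seed,
                             loci = HLA_CLASS_I,
                             alleleFreqs = NULL,
                             nAlleles = 12L,
                             concentration = 0.5,
                             haplotypeFreqs = NULL,
                             inbreeding = 0,
                             groupSizes = c(CALR = 40L, JAK2 = 150L,
                                            CONTROL = 1000L),
                             plantedLogOR = list(),
                             baseline = c(CALR = -3, JAK2 = -2),
                             ageEffect = 0.02, sexEffect = 0.2,
                             ageMean = 60, ageSD = 15, sexRatio = 0.5,
                             brLogRange = list(
                               CALRmut = c(0.05, 40),
                               JAK2V617F = c(0.5, 80)),
                             brCorrelation = 0) {
  stopifnot(inbreeding >= 0, inbreeding < 1,
            brCorrelation >= -1, brCorrelation <= 1,
            all(groupSizes >= 0))
  if (!is.null(alleleFreqs)) {
    for (loc in names(alleleFreqs)) {
      f <- alleleFreqs[[loc]]
      if (abs(sum(f) - 1) > 1e-8 || any(f < 0))
        stop("allele frequencies for ", loc,
             " must be non-negative and sum to 1")
    }
  }
  if (!is.null(haplotypeFreqs)) {
    if (abs(sum(haplotypeFreqs$freq) - 1) > 1e-8 ||
        any(haplotypeFreqs$freq < 0))
      stop("haplotype frequencies must be non-negative and sum to 1")
  }
  structure(list(seed = as.integer(seed), loci = loci,
                 alleleFreqs = alleleFreqs, nAlleles = as.integer(nAlleles),
                 concentration = concentration,
                 haplotypeFreqs = haplotypeFreqs, inbreeding = inbreeding,
                 groupSizes = groupSizes, plantedLogOR = plantedLogOR,
                 baseline = baseline, ageEffect = ageEffect,
                 sexEffect = sexEffect, ageMean = ageMean, ageSD = ageSD,
                 sexRatio = sexRatio, brLogRange = brLogRange,
                 brCorrelation = brCorrelation),
            class = "SimulationConfig")
}

.rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

# Materialise per-locus spectra (explicit or Dirichlet under the
# current RNG state). Allele names follow the synthetic series
# LOCUS*90:01, 90:02, ... to stay clear of real allele catalogues.
.resolveFreqs <- function(config) {
  freqs <- list()
  for (loc in config$loci) {
    if (!is.null(config$alleleFreqs[[loc]])) {
      freqs[[loc]] <- config$alleleFreqs[[loc]]
    } else {
      f <- .rdirichlet1(config$nAlleles, config$concentration)
      names(f) <- formatHlaAllele(rep(loc, config$nAlleles), 90L,
                                  seq_len(config$nAlleles))
      freqs[[loc]] <- f
    }
  }
  freqs
}

.drawHaplotypes <- function(n, config, freqs) {
  out <- list()
  ldLoci <- if (!is.null(config$haplotypeFreqs))
    config$haplotypeFreqs$loci else character()
  if (length(ldLoci)) {
    hf <- config$haplotypeFreqs$freq
    pick <- sample(names(hf), 2L * n, replace = TRUE, prob = hf)
    partsMat <- do.call(rbind, strsplit(pick, "-", fixed = TRUE))
    for (j in seq_along(ldLoci))
      out[[ldLoci[j]]] <- matrix(partsMat[, j], n, 2L)
  }
  for (loc in setdiff(config$loci, ldLoci)) {
    f <- freqs[[loc]]
    out[[loc]] <- matrix(sample(names(f), 2L * n, replace = TRUE,
                                prob = f), n, 2L)
  }
  if (config$inbreeding > 0) {
    for (loc in config$loci) {
      copy <- runif(n) < config$inbreeding
      out[[loc]][copy, 2L] <- out[[loc]][copy, 1L]
    }
  }
  out
}

#' Simulate unphased genotypes
#'
#' Draws \code{n} subjects' genotypes: two haplotypes independently from
#' the haplotype table where one is configured (inducing LD), otherwise
#' two alleles per locus from the per-locus spectra; with inbreeding f
#' the second allele copies the first with probability f per locus.
#' Ages, sexes and a CONTROL placeholder group are attached so the
#' result is a complete \linkS4class{HlaCohort}; deterministic under
#' \code{config$seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param n number of subjects (default: three times the configured
#'   group total, a pool for phenotype rejection sampling).
#' @param name cohort label.
#' @return An \linkS4class{HlaCohort}; attribute \code{freqs} records
#'   the realised spectra.
#' @export
simulateGenotypes <- function(config, n = NULL, name = "sim") {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(n)) n <- 3L * sum(config$groupSizes)
  set.seed(config$seed)
  freqs <- .resolveFreqs(config)
  haps <- .drawHaplotypes(n, config, freqs)
  ids <- sprintf("%s%05d", name, seq_len(n))
  age <- round(pmin(95, pmax(18, rnorm(n, config$ageMean, config$ageSD))))
  sex <- ifelse(runif(n) < config$sexRatio, "M", "F")
  subjects <- data.frame(subject_id = ids, cohort = name,
                         group = "CONTROL", age = age, sex = sex)
  geno <- do.call(rbind, lapply(config$loci, function(loc)
    data.frame(subject_id = ids, locus = loc,
               allele1 = haps[[loc]][, 1L], allele2 = haps[[loc]][, 2L])))
  out <- HlaCohort(name, subjects, geno)
  attr(out, "freqs") <- freqs
  out
}

.diseaseEta <- function(x, config, disease) {
  s <- subjectTable(x)
  eta <- rep(config$baseline[[disease]], nrow(s)) +
    config$ageEffect * (s$age - config$ageMean) +
    config$sexEffect * as.numeric(s$sex == "M")
  planted <- config$plantedLogOR[[disease]]
  if (!is.null(planted) && length(planted)) {
    g <- genotypeTable(x)
    for (a in names(planted)) {
      loc <- sub("\\*.*$", "", a)
      gl <- g[g$locus == loc, ]
      d <- (gl$allele1 == a) + (gl$allele2 == a)
      eta <- eta + planted[[a]] *
        ifelse(is.na(match(s$subject_id, gl$subject_id)), 0,
               d[match(s$subject_id, gl$subject_id)])
    }
  }
  eta
}

#' Assign disease groups by logistic rejection sampling
#'
#' Computes each pool subject's case probability under the two planted
#' logistic disease models (allele log-ORs plus age and sex terms) and
#' assigns groups by rejection: a subject becomes a CALR case with its
#' CALR model probability, otherwise a JAK2 case with its JAK2 model
#' probability, otherwise a control. The first subjects reaching each
#' target count are kept. Case sampling proportional to p and control
#' sampling proportional to (1 - p) preserves the planted odds ratios
#' in retrospective case-control fits.
#'
#' @param x a pool cohort from \code{\link{simulateGenotypes}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return An \linkS4class{HlaCohort} with \code{groupSizes} subjects in
#'   each group.
#' @export
simulatePhenotypes <- function(x, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  pC <- stats::plogis(.diseaseEta(x, config, "CALR"))
  pJ <- stats::plogis(.diseaseEta(x, config, "JAK2"))
  n <- nSubjects(x)
  uC <- runif(n); uJ <- runif(n)
  lab <- ifelse(uC < pC, "CALR", ifelse(uJ < pJ, "JAK2", "CONTROL"))
  s <- subjectTable(x)
  keep <- character(0)
  for (grp in c("CALR", "JAK2", "CONTROL")) {
    want <- config$groupSizes[[grp]]
    got <- s$subject_id[lab == grp]
    if (length(got) < want)
      stop("rejection sampling produced only ", length(got), " ", grp,
           " subjects of ", want, " requested; enlarge the pool")
    keep <- c(keep, got[seq_len(want)])
  }
  s <- s[match(keep, s$subject_id), ]
  s$group <- lab[match(keep, subjectTable(x)$subject_id)]
  g <- genotypeTable(x)
  HlaCohort(cohortName(x), s,
            g[g$subject_id %in% keep, , drop = FALSE])
}

#' Simulate one synthetic study cohort
#'
#' Convenience wrapper: draws a genotype pool and assigns phenotypes,
#' enlarging the pool automatically until the target group sizes are
#' met.
#'
#' @inheritParams simulateGenotypes
#' @return An \linkS4class{HlaCohort}.
#' @export
simulateCohort <- function(config, name = "sim") {
  mult <- 3L
  repeat {
    pool <- simulateGenotypes(config, n = mult * sum(config$groupSizes),
                              name = name)
    out <- tryCatch(simulatePhenotypes(pool, config),
                    error = function(e) e)
    if (is(out, "HlaCohort")) return(out)
    mult <- mult * 3L
    if (mult > 200L) stop(conditionMessage(out))
  }
}

#' Simulate rank tables with a planted cross-mutation BR correlation
#'
#' Per allele, a latent bivariate normal with correlation rho generates
#' the pair of log best ranks (one per mutation), each mapped to its
#' configured log-uniform range. Peptide-level ranks are then filled in
#' so that the minimum over each mutation's peptide set equals the
#' drawn BR exactly: the first peptide carries the BR, all others draw
#' above it. Deterministic under \code{config$seed}.
#'
#' @param alleles character vector of allele names.
#' @param psets named list of \linkS4class{PeptideSet}s (one per
#'   mutation; names must match \code{config$brLogRange}).
#' @param config a \code{\link{simulationConfig}}.
#' @return A list per mutation: \code{table} (a
#'   \linkS4class{RankTable}) and \code{br} (the drawn allele-level
#'   BRs, the planted truth).
#' @export
simulateRankTable <- function(alleles, psets, config) {
  stopifnot(inherits(config, "SimulationConfig"),
            all(names(psets) %in% names(config$brLogRange)))
  alleles <- parseHlaAllele(alleles)$allele
  set.seed(config$seed + 2L)
  rho <- config$brCorrelation
  nA <- length(alleles)
  z1 <- rnorm(nA)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nA)
  zs <- list(z1, z2)
  out <- list()
  for (j in seq_along(psets)) {
    m <- names(psets)[j]
    rng <- config$brLogRange[[m]]
    q <- pnorm(zs[[min(j, 2L)]])
    br <- exp(log(rng[1]) + q * (log(rng[2]) - log(rng[1])))
    peps <- peptides(psets[[m]])
    if (length(peps) == 0L) stop("empty peptide set for ", m)
    rows <- lapply(seq_len(nA), function(i) {
      other <- if (length(peps) > 1L)
        br[i] + runif(length(peps) - 1L) * (100 - br[i]) else numeric(0)
      data.frame(allele = alleles[i], peptide = peps,
                 percent_rank = c(br[i], other))
    })
    out[[m]] <- list(table = RankTable(do.call(rbind, rows)),
                     br = setNames(br, alleles))
  }
  out
}

#' Simulate binding-groove sequences for divergence analyses
#'
#' Per locus, a random base sequence of the requested length is drawn
#' and each allele's sequence mutates each position away from the base
#' with probability \code{divergenceScale}; at scale 0 all alleles of a
#' locus are identical (HED 0 everywhere), and expected pairwise
#' divergence grows monotonically with the scale.
#'
#' @param alleles character vector of allele names (any loci).
#' @param length sequence length (default 90, the size of a class I
#'   alpha1+alpha2 groove alignment block).
#' @param divergenceScale per-site mutation probability in [0, 1].
#' @param seed integer seed.
#' @return An \linkS4class{AlleleSequenceDB}.
#' @export
simulateSequences <- function(alleles, length = 90L, divergenceScale = 0.1,
                              seed = 1L) {
  parsed <- parseHlaAllele(alleles)
  set.seed(seed)
  AA <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  seqs <- character(nrow(parsed))
  for (loc in unique(parsed$locus)) {
    base <- sample(AA, length, replace = TRUE)
    idx <- which(parsed$locus == loc)
    for (i in idx) {
      s <- base
      hit <- runif(length) < divergenceScale
      if (any(hit)) s[hit] <- sample(AA, sum(hit), replace = TRUE)
      seqs[i] <- paste(s, collapse = "")
    }
  }
  names(seqs) <- parsed$allele
  AlleleSequenceDB(seqs)
}

#' Write a complete miniature synthetic study to disk
#'
#' Generates three cohorts, a sequence FASTA, rank tables for both
#' built-in mutations and a manifest recording the seed and planted
#' parameters, all in the package's external interchange dialects, so
#' the full pipeline can run end-to-end from files in well under a
#' minute.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed recorded in the manifest.
#' @return Invisibly, a named list of the written file paths.
#' @export
generateFixtureSuite <- function(outDir, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  cohortNames <- c("alpha", "beta", "gamma")
  # fixed locus A spectrum so the planted allele is common by design;
  # B and C spectra are Dirichlet-drawn under the run seed
  freqA <- setNames(c(0.22, 0.18, 0.14, 0.11, 0.09, 0.07, 0.06, 0.05,
                      0.04, 0.02, 0.01, 0.01), sprintf("A*90:%02d", 1:12))
  freqs <- list(A = freqA)
  alleleUniverse <- character(0)
  for (i in seq_along(cohortNames)) {
    cfg <- simulationConfig(
      seed = seed + i,
      groupSizes = c(CALR = 15L, JAK2 = 25L, CONTROL = 60L),
      alleleFreqs = freqs,
      plantedLogOR = list(CALR = setNames(-0.9, "A*90:01")))
    cohort <- simulateCohort(cfg, name = cohortNames[i])
    if (length(freqs) == 1L)
      freqs <- attr(simulateGenotypes(cfg, n = 1L), "freqs")
    p <- file.path(outDir, paste0("genotypes_", cohortNames[i], ".tsv"))
    writeGenotypeTable(cohort, p)
    paths[[paste0("genotypes_", cohortNames[i])]] <- p
    alleleUniverse <- union(alleleUniverse, cohortAlleles(cohort))
  }
  alleleUniverse <- sort(alleleUniverse)
  db <- simulateSequences(alleleUniverse, seed = seed)
  pFa <- file.path(outDir, "allele_sequences.fasta")
  Biostrings::writeXStringSet(db@sequences, pFa)
  paths$sequences <- pFa
  psets <- list(CALRmut = enumerateNeoTerminus(calrNeoContext()),
                JAK2V617F = enumeratePointMutation(jak2V617FContext()))
  cfgR <- simulationConfig(seed = seed, brCorrelation = -0.6)
  rt <- simulateRankTable(alleleUniverse, psets, cfgR)
  for (m in names(rt)) {
    p <- file.path(outDir, paste0("ranks_", m, ".tsv"))
    writeRankTable(rt[[m]]$table, p)
    paths[[paste0("ranks_", m)]] <- p
  }
  manifest <- c(
    paste0("seed\t", seed),
    "planted_log_or\tA*90:01=-0.9\tcomparison=CALR",
    "br_correlation\t-0.6",
    paste0("cohorts\t", paste(cohortNames, collapse = ",")),
    paste0("alleles\t", length(alleleUniverse)))
  pMan <- file.path(outDir, "manifest.tsv")
  writeLines(manifest, pMan)
  paths$manifest <- pMan
  invisible(paths)
}
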