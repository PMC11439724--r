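test_that("the generator is deterministic under its seed", {
  cfg <- simulationConfig(seed = 121, groupSizes = c(CALR = 20L, JAK2 = 30L,
                                                     CONTROL = 50L))
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(subjectTable(c1), subjectTable(c2))
  expect_identical(genotypeTable(c1), genotypeTable(c2))
  # a different seed changes the draw
  c3 <- simulateCohort(simulationConfig(seed = 122,
                                        groupSizes = c(CALR = 20L,
                                                       JAK2 = 30L,
                                                       CONTROL = 50L)))
  expect_false(identical(genotypeTable(c1), genotypeTable(c3)))
  # group sizes are exactly as requested
  expect_equal(groupCounts(c1), c(CALR = 20L, JAK2 = 30L, CONTROL = 50L))
})

test_that("config validation rejects malformed frequency inputs", {
  expect_error(simulationConfig(seed = 1,
                                alleleFreqs = list(A = c("A*90:01" = 0.7))),
               "sum to 1")
  expect_error(simulationConfig(seed = 1, inbreeding = 1), "inbreeding")
  expect_error(simulationConfig(seed = 1, brCorrelation = -2),
               "brCorrelation")
})

test_that("without inbreeding the HWE test is calibrated; with it, not", {
  f <- setNames(c(0.45, 0.30, 0.15, 0.10), sprintf("A*90:%02d", 1:4))
  ps <- unlist(lapply(1:30, function(s) {
    cfg <- simulationConfig(seed = 2000 + s, loci = "A",
                            alleleFreqs = list(A = f),
                            groupSizes = c(CALR = 0L, JAK2 = 0L,
                                           CONTROL = 300L))
    co <- simulateCohort(cfg)
    filterAlleles(co, "A", hweGroup = NULL)$hwe_p
  }))
  # under HWE the exact p-values are super-uniform but rarely small
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps > 0.5), 0.30)
  # strong inbreeding produces a systematic heterozygote deficit
  cfgF <- simulationConfig(seed = 2100, loci = "A",
                           alleleFreqs = list(A = f), inbreeding = 0.4,
                           groupSizes = c(CALR = 0L, JAK2 = 0L,
                                          CONTROL = 600L))
  coF <- simulateCohort(cfgF)
  g <- genotypesAt(coF, "A")
  hetFrac <- mean(g$allele1 != g$allele2)
  hetExp <- 1 - sum(f^2)
  expect_lt(hetFrac, 0.85 * hetExp)
  expect_true(any(filterAlleles(coF, "A", hweGroup = NULL)$hwe_p < 0.01))
})

test_that("planted allele effects shift case frequencies as configured", {
  cfg <- simulationConfig(seed = 131, loci = "A",
                          groupSizes = c(CALR = 300L, JAK2 = 0L,
                                         CONTROL = 600L),
                          baseline = c(CALR = 0, JAK2 = -30),
                          plantedLogOR = list(CALR = c("A*90:01" = -0.92)))
  co <- simulateCohort(cfg)
  ac <- alleleCounts(co, "A")
  s <- subjectTable(co)
  g <- genotypesAt(co, "A")
  frq <- function(grp) {
    gi <- g[g$subject_id %in% s$subject_id[s$group == grp], ]
    mean(c(gi$allele1, gi$allele2) == "A*90:01")
  }
  expect_lt(frq("CALR"), frq("CONTROL"))
  # null configuration: no systematic difference (within sampling noise)
  cfg0 <- simulationConfig(seed = 132, loci = "A",
                           groupSizes = c(CALR = 300L, JAK2 = 0L,
                                          CONTROL = 600L),
                           baseline = c(CALR = 0, JAK2 = -30))
  co0 <- simulateCohort(cfg0)
  g0 <- genotypesAt(co0, "A")
  s0 <- subjectTable(co0)
  f1 <- mean(c(g0$allele1, g0$allele2)[rep(
    s0$group[match(g0$subject_id, s0$subject_id)], 2) == "CALR"] == "A*90:01")
  f0 <- mean(c(g0$allele1, g0$allele2)[rep(
    s0$group[match(g0$subject_id, s0$subject_id)], 2) == "CONTROL"] == "A*90:01")
  expect_lt(abs(f1 - f0), 0.08)
})

test_that("simulated rank tables realise the drawn best ranks exactly", {
  alleles <- sprintf("C*90:%02d", 1:30)
  psets <- list(CALRmut = enumerateNeoTerminus(calrNeoContext(), 9, 9),
                JAK2V617F = enumeratePointMutation(jak2V617FContext(), 9, 9))
  cfg <- simulationConfig(seed = 141, brCorrelation = -0.6)
  rt <- simulateRankTable(alleles, psets, cfg)
  for (m in names(rt)) {
    rng <- cfg$brLogRange[[m]]
    expect_true(all(rt[[m]]$br >= rng[1] & rt[[m]]$br <= rng[2]))
    for (a in alleles[c(1, 15, 30)]) {
      br <- bestRank(rt[[m]]$table, a, psets[[m]])$br
      expect_equal(br, unname(rt[[m]]$br[a]), tolerance = 1e-12)
    }
  }
  # deterministic under seed
  rt2 <- simulateRankTable(alleles, psets, cfg)
  expect_identical(rt[[1]]$br, rt2[[1]]$br)
})

test_that("the planted cross-mutation BR correlation is recovered", {
  alleles <- sprintf("B*90:%02d", 1:200)
  psets <- list(CALRmut = enumerateNeoTerminus(calrNeoContext(), 9, 9),
                JAK2V617F = enumeratePointMutation(jak2V617FContext(), 9, 9))
  cfg <- simulationConfig(seed = 151, brCorrelation = -0.6)
  rt <- simulateRankTable(alleles, psets, cfg)
  r <- cor(log(rt$CALRmut$br), log(rt$JAK2V617F$br))
  expect_lt(abs(r - (-0.6)), 0.15)
  # degenerate planting: perfect rank anticorrelation
  cfg1 <- simulationConfig(seed = 151, brCorrelation = -1)
  rt1 <- simulateRankTable(alleles, psets, cfg1)
  expect_equal(cor(log(rt1$CALRmut$br), log(rt1$JAK2V617F$br),
                   method = "spearman"), -1, tolerance = 1e-12)
})

test_that("the fixture suite loads cleanly and records its seed", {
  outDir <- withr::local_tempdir()
  paths <- generateFixtureSuite(outDir, seed = 17)
  for (cn in c("alpha", "beta", "gamma")) {
    co <- expect_silent(readGenotypeTable(paths[[paste0("genotypes_", cn)]]))
    expect_gt(nSubjects(co), 0)
  }
  db <- readImgtProteinFasta(paths$sequences)
  expect_gt(length(dbAlleles(db)), 0)
  for (m in c("CALRmut", "JAK2V617F")) {
    rt <- readRankTable(paths[[paste0("ranks_", m)]])
    expect_gt(nrow(rankEntries(rt)), 0)
  }
  manifest <- readLines(paths$manifest)
  expect_true(any(grepl("^seed\t17$", manifest)))
})
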