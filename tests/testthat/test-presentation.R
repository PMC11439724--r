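test_that("simple TSV rank tables read, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("allele\tpeptide\tpercent_rank",
               "A*02:01\tRMMRTKMRM\t0.4",
               "A*02:01\tSPARPRTSC\t5",
               "B*35:01\tRMMRTKMRM\t30"), path)
  rt <- readRankTable(path)
  expect_equal(nrow(rankEntries(rt)), 3L)
  out <- withr::local_tempfile(fileext = ".tsv")
  writeRankTable(rt, out)
  expect_equal(rankEntries(readRankTable(out)), rankEntries(rt))
  # conflicting duplicates fail, equal duplicates collapse
  writeLines(c("allele\tpeptide\tpercent_rank",
               "A*02:01\tRMMRTKMRM\t0.4", "A*02:01\tRMMRTKMRM\t0.5"), path)
  expect_error(readRankTable(path), "conflicting")
  writeLines(c("allele\tpeptide\tpercent_rank",
               "A*02:01\tRMMRTKMRM\t0.4", "A*02:01\tRMMRTKMRM\t0.4"), path)
  expect_equal(nrow(rankEntries(readRankTable(path))), 1L)
  writeLines(c("allele\tpeptide\tpercent_rank", "A*02:01\tRMM\t-1"), path)
  expect_error(readRankTable(path), "positive")
})

test_that("the predictor tab export dialect parses by column blocks", {
  path <- withr::local_tempfile(fileext = ".xls")
  writeLines(c(
    "# predictor export",
    "\t\t\tA*02:01\t\t\t\tB*07:02\t\t\t",
    paste("Pos", "Peptide", "ID", "core", "icore", "EL-score", "EL_Rank",
          "core", "icore", "EL-score", "EL_Rank", sep = "\t"),
    paste(1, "RMMRTKMRM", "pep1", "RMMRTKMRM", "RMMRTKMRM", "0.2", "1.5",
          "RMMRTKMRM", "RMMRTKMRM", "0.1", "12", sep = "\t"),
    paste(2, "SPARPRTSC", "pep2", "SPARPRTSC", "SPARPRTSC", "0.6", "0.3",
          "SPARPRTSC", "SPARPRTSC", "0.2", "7.5", sep = "\t"),
    paste(3, "MRMRRMRRT", "pep3", "MRMRRMRRT", "MRMRRMRRT", "0.1", "22",
          "MRMRRMRRT", "MRMRRMRRT", "0.1", "44", sep = "\t"),
    paste(4, "RRKMSPARP", "pep4", "RRKMSPARP", "RRKMSPARP", "0.1", "3",
          "RRKMSPARP", "RRKMSPARP", "0.1", "9", sep = "\t")), path)
  rt <- readRankTable(path, dialect = "netmhcpan_tab")
  r <- rankEntries(rt)
  expect_equal(nrow(r), 8L)  # 2 alleles x 4 peptides
  expect_equal(r$percent_rank[r$allele == "A*02:01" &
                                r$peptide == "SPARPRTSC"], 0.3)
  expect_equal(r$percent_rank[r$allele == "B*07:02" &
                                r$peptide == "MRMRRMRRT"], 44)
})

test_that("mock predictor is deterministic, complete, and plantable", {
  alleles <- c("A*02:01", "B*07:02", "C*06:02")
  peps <- peptides(enumerateNeoTerminus(calrNeoContext()))
  t1 <- mockRankPredictor(alleles, peps, seed = 5)
  t2 <- mockRankPredictor(alleles, peps, seed = 5)
  expect_identical(rankEntries(t1), rankEntries(t2))
  expect_equal(nrow(rankEntries(t1)), length(alleles) * length(peps))
  r <- rankEntries(t1)$percent_rank
  expect_true(all(r > 0 & r <= 100))
  # a different seed moves the ranks
  t3 <- mockRankPredictor(alleles, peps, seed = 6)
  expect_false(identical(rankEntries(t1)$percent_rank,
                         rankEntries(t3)$percent_rank))
  planted <- data.frame(allele = "A*02:01", peptide = "RMMRTKMRM",
                        percent_rank = 0.1)
  t4 <- mockRankPredictor(alleles, peps, seed = 5, planted = planted)
  r4 <- rankEntries(t4)
  expect_equal(r4$percent_rank[r4$allele == "A*02:01" &
                                 r4$peptide == "RMMRTKMRM"], 0.1)
  expect_error(mockRankPredictor(alleles, peps, 5,
                                 data.frame(allele = "A*02:01",
                                            peptide = "RMMRTKMRM",
                                            percent_rank = 0)),
               "\\(0, 100\\]")
})

test_that("best rank is the minimum over the peptide set", {
  peps <- c("RMMRTKMRM", "SPARPRTSC", "MRMRRMRRT")
  ps <- enumerateNeoTerminus(calrNeoContext(), 9, 9)
  rt <- RankTable(data.frame(
    allele = "A*02:01", peptide = peptides(ps),
    percent_rank = seq(0.4, by = 0.7, length.out = length(peptides(ps)))))
  br <- bestRank(rt, "A*02:01", ps)
  expect_equal(br$br, 0.4)
  expect_equal(br$mutation_id, "CALRmut")
  expect_error(bestRank(rt, "B*07:02", ps), "no predictions")
  # randomized tables match an exhaustive scan
  set.seed(21)
  for (rep in 1:5) {
    pr <- runif(length(peptides(ps)), 0.01, 100)
    rti <- RankTable(data.frame(allele = "C*06:02",
                                peptide = peptides(ps), percent_rank = pr))
    expect_equal(bestRank(rti, "C*06:02", ps)$br, min(pr))
  }
  # coverage control: missing peptides fail unless imputed
  rtp <- RankTable(data.frame(allele = "A*02:01", peptide = peps,
                              percent_rank = c(5, 0.4, 30)))
  expect_error(bestRank(rtp, "A*02:01", ps), "lack predictions")
  expect_equal(bestRank(rtp, "A*02:01", ps, missingRank = 100)$br, 0.4)
})

test_that("the harmonic-mean score matches closed forms", {
  expect_equal(harmonicMeanBR(rep(2, 6)), 2)
  expect_equal(harmonicMeanBR(c(0.5, 1, 2, 4, 8, 16)),
               6 / (2 + 1 + 0.5 + 0.25 + 0.125 + 0.0625),
               tolerance = 1e-15)
  expect_equal(harmonicMeanBR(c(1, 1, 10, 10, 10, 10)), 2.5)
  expect_error(harmonicMeanBR(c(1, -1)), "positive")
})

test_that("PHBR is permutation-invariant, monotone and mean-bounded", {
  set.seed(31)
  for (rep in 1:20) {
    brs <- runif(6, 0.05, 60)
    h <- harmonicMeanBR(brs)
    expect_equal(harmonicMeanBR(sample(brs)), h)
    expect_gte(h, min(brs)); expect_lte(h, max(brs))
    expect_lte(h, mean(brs))  # harmonic <= arithmetic
    bumped <- brs; bumped[3] <- bumped[3] * 1.5
    expect_gt(harmonicMeanBR(bumped), h)
  }
  expect_equal(harmonicMeanBR(rep(7, 6)), mean(rep(7, 6)))
})

test_that("subject PHBR duplicates homozygous alleles and demands all loci", {
  co <- makeToyCohort()
  brTab <- data.frame(allele = c("A*01:01", "A*02:01", "B*08:01",
                                 "B*35:01", "C*06:02", "C*07:01"),
                      br = c(1, 1, 10, 10, 10, 10))
  # S2 is homozygous A*01:01 (br 1) and C*07:01 (br 10)
  r <- subjectPhbr(co, "S2", brTab, "CALRmut")
  expect_equal(r$phbr, 6 / (1 + 1 + 0.1 + 0.1 + 0.1 + 0.1), tolerance = 1e-12)
  expect_equal(r$n_alleles_used, 6L)
  expect_error(subjectPhbr(co, "S5", brTab, "CALRmut"), "locus.*C")
})

test_that("cohort PHBR table enumerates subject-mutation pairs and skips", {
  co <- makeToyCohort()
  psets <- list(CALRmut = enumerateNeoTerminus(calrNeoContext(), 9, 9),
                JAK2V617F = enumeratePointMutation(jak2V617FContext(), 9, 9))
  alleles <- cohortAlleles(co, HLA_CLASS_I)
  tabs <- lapply(psets, function(ps)
    mockRankPredictor(alleles, peptides(ps), seed = 3))
  ph <- cohortPhbrTable(co, tabs, psets)
  expect_equal(nrow(ph), 8L)  # 4 complete subjects x 2 mutations
  sk <- attr(ph, "skipped")
  expect_equal(sk$subject_id, "S5")
  # rows agree with independent per-subject recomputation
  for (i in seq_len(nrow(ph))) {
    m <- ph$mutation_id[i]
    brTab <- alleleBestRanks(tabs[[m]], alleles, psets[[m]])
    expect_equal(ph$phbr[i],
                 subjectPhbr(co, ph$subject_id[i], brTab, m)$phbr)
  }
})

test_that("binder categories apply inclusive thresholds", {
  expect_equal(as.character(categorizeBinder(c(0.3, 0.5, 0.51, 2, 2.0001, 5))),
               c("SB", "SB", "WB", "WB", "NB", "NB"))
  expect_error(categorizeBinder(0), "positive")
})
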