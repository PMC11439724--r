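test_that("allele parsing canonicalises, truncates and round-trips", {
  p <- parseHlaAllele(c("C*06:02", "HLA-A*02:01:01:02", "B*35:01"))
  expect_equal(p$locus, c("C", "A", "B"))
  expect_equal(p$field1, c(6L, 2L, 35L))
  expect_equal(p$field2, c(2L, 1L, 1L))
  expect_equal(p$allele, c("C*06:02", "A*02:01", "B*35:01"))
  # canonical strings are fixed points
  expect_equal(parseHlaAllele(p$allele)$allele, p$allele)
  # expression suffixes stripped with a flag
  q <- parseHlaAllele("B*44:02N")
  expect_true(q$suffix_stripped)
  expect_equal(q$allele, "B*44:02")
  expect_false(p$suffix_stripped[1])
})

test_that("malformed allele strings fail with informative errors", {
  expect_error(parseHlaAllele("X*01:01"), "unknown HLA locus.*X\\*01:01")
  expect_error(parseHlaAllele("A-01:01"), "missing '\\*'")
  expect_error(parseHlaAllele("A*0101"), "two.*fields")
  expect_error(parseHlaAllele(""), "non-empty")
})

test_that("locus class assignment is correct", {
  expect_equal(hlaClass(c("A", "B", "C")), rep("I", 3))
  expect_equal(hlaClass(c("DPB1", "DQA1", "DQB1", "DRB1")), rep("II", 4))
  expect_equal(hlaClass("C*06:02"), "I")
  expect_error(hlaClass("Z"), "unknown")
})

test_that("genotype table writer and reader round-trip a cohort", {
  co <- makeToyCohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(co, path)
  back <- readGenotypeTable(path)
  expect_equal(subjectTable(back), subjectTable(co))
  expect_equal(genotypeTable(back)[order(genotypeTable(back)$subject_id,
                                         genotypeTable(back)$locus), ],
               genotypeTable(co)[order(genotypeTable(co)$subject_id,
                                       genotypeTable(co)$locus), ],
               ignore_attr = TRUE)
})

test_that("reader handles missing values and rejects bad tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject_id\tcohort\tgroup\tage\tsex\tA_1\tA_2\tB_1\tB_2",
    "P1\tx\tCALR\t\tM\tA*01:01\tA*02:01\tB*08:01\tB*35:01",
    "P2\tx\tCONTROL\t50\t\tA*01:01\t\tB*08:01\tB*08:01"), path)
  expect_warning(co <- readGenotypeTable(path), "one missing allele")
  s <- subjectTable(co)
  expect_true(is.na(s$age[s$subject_id == "P1"]))   # retained with NA age
  g <- genotypeTable(co)
  expect_false(any(g$subject_id == "P2" & g$locus == "A"))  # locus dropped
  expect_true(any(g$subject_id == "P2" & g$locus == "B"))

  writeLines(c("subject_id\tcohort\tgroup\tage\tsex",
               "P1\tx\tCALR\t60\tM", "P1\tx\tCALR\t61\tM"), path)
  expect_error(readGenotypeTable(path), "duplicate subject_id")
  writeLines(c("subject_id\tcohort\tgroup\tage\tsex",
               "P1\tx\tMPN\t60\tM"), path)
  expect_error(readGenotypeTable(path), "CALR, JAK2, CONTROL")
  writeLines(c("subject_id\tgroup", "P1\tCALR"), path)
  expect_error(readGenotypeTable(path), "mandatory columns")
})

test_that("IMGT FASTA reader keeps the first record per two-field allele", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">HLA:HLA00001 A*01:01:01:01 described",
    "ARNDCQEGHIL",
    ">HLA:HLA00002 A*01:01:01:02 described",
    "ARNDCQEGHIV",
    ">HLA:HLA00005 A*02:01:01:01 described",
    "GRNDCQEGHIL"), path)
  db <- readImgtProteinFasta(path)
  expect_setequal(dbAlleles(db), c("A*01:01", "A*02:01"))
  expect_equal(alleleSequence(db, "A*01:01"), "ARNDCQEGHIL")  # first kept
})

test_that("FASTA reader enforces per-locus lengths and flags bad records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A*01:01", "ARNDC", ">A*02:01", "ARND"), path)
  expect_error(readImgtProteinFasta(path), "unequal extracted lengths")
  writeLines(c(">A*01:01", "ARNDC", ">A*02:01", "ARNDX"), path)
  expect_warning(db <- readImgtProteinFasta(path), "non-standard")
  expect_equal(dbAlleles(db), "A*01:01")
  writeLines(character(0), path)
  expect_warning(db0 <- readImgtProteinFasta(path), "empty FASTA")
  expect_length(dbAlleles(db0), 0)
})

test_that("domain range extraction restricts sequences per locus", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A*01:01", "MMARNDCQEGHIL", ">A*02:01", "MMGRNDCQEGHIV"),
             path)
  db <- readImgtProteinFasta(path, domainRanges = list(A = c(3, 8)))
  expect_equal(alleleSequence(db, "A*01:01"), "ARNDCQ")
  expect_equal(alleleSequence(db, "A*02:01"), "GRNDCQ")
})

test_that("allele counting matches closed forms and sums to one", {
  co <- makeToyCohort()
  ac <- alleleCounts(co, "A")
  # 5 subjects typed at A: S2 hom A*01:01, others het 01:01/02:01 (x3), S3 hom 02:01
  expect_equal(ac$count[ac$allele == "A*01:01"], 5L)
  expect_equal(ac$count[ac$allele == "A*02:01"], 5L)
  expect_equal(sum(ac$frequency), 1, tolerance = 1e-12)
  expect_equal(ac$carriers[ac$allele == "A*01:01"], 4L)
  # homozygous-only cohort: frequency 1
  subj <- data.frame(subject_id = c("a", "b"), cohort = "z",
                     group = "CONTROL", age = 50, sex = "F")
  g <- data.frame(subject_id = c("a", "b"), locus = "A",
                  allele1 = "A*02:01", allele2 = "A*02:01")
  expect_equal(alleleCounts(HlaCohort("z", subj, g), "A")$frequency, 1)
  expect_error(alleleCounts(HlaCohort("z", subj, g[0, ]), "A"),
               "no subject typed")
})

test_that("empirical frequencies of a simulated cohort stay within 3 SE", {
  f <- setNames(c(0.5, 0.3, 0.15, 0.05), sprintf("A*90:%02d", 1:4))
  cfg <- simulationConfig(seed = 101, loci = "A", alleleFreqs = list(A = f),
                          groupSizes = c(CALR = 0L, JAK2 = 0L,
                                         CONTROL = 2000L))
  co <- simulateCohort(cfg)
  ac <- alleleCounts(co, "A")
  n2 <- 2 * nSubjects(co)
  for (a in names(f)) {
    se <- sqrt(f[[a]] * (1 - f[[a]]) / n2)
    expect_lt(abs(ac$frequency[ac$allele == a] - f[[a]]), 3 * se + 1e-12)
  }
})

test_that("cohort container validates and reports structure", {
  co <- makeToyCohort()
  expect_equal(nSubjects(co), 5L)
  expect_equal(groupCounts(co), c(CALR = 2L, JAK2 = 1L, CONTROL = 2L))
  expect_output(show(co), "5 subjects")
  # unordered allele pairs: input order does not matter
  g <- genotypeTable(co)
  expect_true(all(g$allele1 <= g$allele2))
  s <- subjectTable(co)
  s$age[1] <- 300
  expect_error(HlaCohort("bad", s, g), "age")
})
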