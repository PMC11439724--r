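test_that("HWE exact test matches the log-factorial oracle", {
  expect_equal(hweExactTest(0, 0, 100), 1)
  expect_lt(hweExactTest(25, 0, 25), 1e-10)  # total heterozygote deficit
  expect_equal(hweExactTest(5, 10, 5), hweOracleP(5, 10, 5))
  expect_error(hweExactTest(-1, 0, 2), "non-negative")
  expect_error(hweExactTest(0, 0, 0), "at least one")
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(1:120, 1)
    nAA <- sample(0:n, 1)
    nAB <- sample(0:(n - nAA), 1)
    nBB <- n - nAA - nAB
    expect_equal(hweExactTest(nAA, nAB, nBB), hweOracleP(nAA, nAB, nBB),
                 tolerance = 1e-12)
  }
})

test_that("dosage matrices conserve two copies per typed locus", {
  co <- makeToyCohort()
  dm <- dosageMatrix(co, "A")
  expect_equal(dm["S2", "A*01:01"], 2L)   # homozygote
  expect_equal(dm["S1", "A*01:01"], 1L)   # heterozygote carrier
  expect_equal(dm["S3", "A*01:01"], 0L)
  expect_true(all(rowSums(dm, na.rm = TRUE)[!is.na(dm[, 1])] == 2))
  dmC <- dosageMatrix(co, "C")
  expect_true(all(is.na(dmC["S5", ])))    # untyped subject marked missing
})

test_that("allele filters label exclusions with their reason", {
  f <- setNames(c(0.55, 0.30, 0.10, 0.04, 0.01),
                sprintf("A*90:%02d", 1:5))
  cfg <- simulationConfig(seed = 61, loci = "A", alleleFreqs = list(A = f),
                          groupSizes = c(CALR = 100L, JAK2 = 0L,
                                         CONTROL = 400L),
                          baseline = c(CALR = 0, JAK2 = -30))
  co <- simulateCohort(cfg)
  filt <- filterAlleles(co, "A")
  rare <- filt[filt$allele == "A*90:05", ]
  expect_equal(rare$filter_status, "EXCLUDED_FREQ")
  expect_true(all(filt$filter_status[filt$frequency >= 0.02] %in%
                    c("TESTED", "EXCLUDED_HWE")))
  # strong inbreeding: heterozygote deficit trips the HWE gate
  cfgF <- simulationConfig(seed = 62, loci = "A", alleleFreqs = list(A = f),
                           inbreeding = 0.5,
                           groupSizes = c(CALR = 0L, JAK2 = 0L,
                                          CONTROL = 800L))
  coF <- simulateCohort(cfgF)
  filtF <- filterAlleles(coF, "A", hweGroup = "CONTROL")
  expect_true(any(filtF$filter_status == "EXCLUDED_HWE"))
  expect_error(filterAlleles(co, "A", hweGroup = "JAK2"), "no subjects")
})

test_that("a monomorphic allele passes filters but cannot be fit", {
  subjects <- data.frame(subject_id = sprintf("m%02d", 1:20), cohort = "t",
                         group = rep(c("CALR", "CONTROL"), 10),
                         age = 50, sex = "F")
  g <- data.frame(subject_id = subjects$subject_id, locus = "A",
                  allele1 = "A*01:01", allele2 = "A*01:01")
  co <- HlaCohort("t", subjects, g)
  filt <- filterAlleles(co, "A")
  expect_equal(filt$filter_status, "TESTED")  # freq 1, HWE p 1
  res <- associateAlleles(co, "CALR", "CONTROL", loci = "A",
                          useCovariates = FALSE)
  expect_equal(res$filter_status, "NOT_CONVERGED")  # zero-variance dosage
  expect_true(is.na(res$log_or))
})

test_that("the additive GLM recovers planted effects and flags separation", {
  set.seed(71)
  n <- 1200
  d <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 60, 12)
  sex <- ifelse(runif(n) < 0.5, "M", "F")
  eta <- -0.5 - 0.9 * d + 0.02 * (age - 60) + 0.2 * (sex == "M")
  y <- rbinom(n, 1, plogis(eta))
  fit <- fitAdditiveGlm(d, y, age, sex)
  expect_true(fit$converged)
  expect_lt(abs(fit$log_or - (-0.9)), 3 * fit$se)
  expect_equal(fit$or_, exp(fit$log_or))
  expect_true(fit$ci95_low < fit$or_ && fit$or_ < fit$ci95_high)
  # matches the reference fitter exactly
  ref <- glm(y ~ d + age + I(sex == "M"), family = binomial)
  expect_equal(fit$log_or, unname(coef(ref)["d"]), tolerance = 1e-8)
  expect_equal(fit$se, unname(summary(ref)$coefficients["d", 2]),
               tolerance = 1e-8)
  # complete separation: allele present only in cases
  ys <- c(rep(1, 30), rep(0, 70))
  ds <- c(rep(2, 30), rep(0, 70))
  sep <- fitAdditiveGlm(ds, ys)
  expect_false(sep$converged)
  expect_true(is.na(sep$log_or))
})

test_that("swapping case and control labels negates the log odds ratio", {
  cfg <- simulationConfig(seed = 81, loci = "A",
                          groupSizes = c(CALR = 120L, JAK2 = 0L,
                                         CONTROL = 240L),
                          baseline = c(CALR = 0, JAK2 = -30),
                          plantedLogOR = list(
                            CALR = c("A*90:01" = -0.7)))
  co <- simulateCohort(cfg)
  a1 <- associateAlleles(co, "CALR", "CONTROL", loci = "A")
  a2 <- associateAlleles(co, "CONTROL", "CALR", loci = "A",
                         hweGroup = "CALR")
  t1 <- a1[a1$filter_status == "TESTED", ]
  t2 <- a2[match(t1$term, a2$term), ]
  both <- t2$filter_status == "TESTED"
  expect_gt(sum(both), 0)
  expect_equal(t1$log_or[both], -t2$log_or[both], tolerance = 1e-6)
})

test_that("a planted protective allele dominates the allele scan", {
  f <- setNames(c(0.15, 0.20, 0.17, 0.13, 0.10, 0.08, 0.06, 0.05, 0.03,
                  0.03), sprintf("A*90:%02d", 1:10))
  hits <- vapply(1:10, function(s) {
    cfg <- simulationConfig(seed = 900 + s, loci = "A",
                            alleleFreqs = list(A = f),
                            groupSizes = c(CALR = 150L, JAK2 = 0L,
                                           CONTROL = 600L),
                            baseline = c(CALR = 0, JAK2 = -30),
                            plantedLogOR = list(
                              CALR = c("A*90:01" = -1.2)))
    co <- simulateCohort(cfg)
    res <- associateAlleles(co, "CALR", "CONTROL", loci = "A")
    res <- res[res$filter_status == "TESTED", ]
    res$term[which.min(res$p_wald)] == "A*90:01" &&
      res$log_or[res$term == "A*90:01"] < 0
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("category association conserves six copies and needs no filter", {
  co <- makeToyCohort()
  alleles <- cohortAlleles(co, HLA_CLASS_I)
  ann <- rbind(
    data.frame(allele = alleles, mutation_id = "CALRmut",
               category = c("SB", "WB", "NB", "NB", "SB", "WB")),
    data.frame(allele = alleles, mutation_id = "JAK2V617F",
               category = "NB"))
  res <- associateCategories(co, ann, "CALR", "CONTROL")
  expect_equal(nrow(res), 6L)  # 2 mutations x 3 categories
  # all-NB mutation: dosage 6 for everyone, flagged as untestable
  jk <- res[res$term == "JAK2V617F_NB", ]
  expect_equal(jk$filter_status, "NOT_CONVERGED")
  expect_equal(jk$freq_case, 1)  # 6 of 6 copies
  # per-subject category dosages sum to six per mutation
  g <- genotypeTable(co)
  g <- g[g$locus %in% HLA_CLASS_I & g$subject_id != "S5", ]
  cat6 <- setNames(ann$category[ann$mutation_id == "CALRmut"], alleles)
  for (sid in unique(g$subject_id)) {
    copies <- c(g$allele1[g$subject_id == sid], g$allele2[g$subject_id == sid])
    expect_equal(length(copies), 6L)
    expect_equal(sum(table(cat6[copies])), 6L)
  }
  expect_error(associateCategories(co, ann[-1, ], "CALR", "CONTROL"),
               "unannotated")
})
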