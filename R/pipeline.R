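#' Validate a study run configuration
#'
#' @param genotypes character vector of genotype TSV paths (one per
#'   cohort).
#' @param sequences optional allele protein FASTA for divergence
#'   analyses.
#' @param ranks optional named list of rank-table TSV paths per
#'   mutation id; when NULL the built-in mock predictor is used with
#'   \code{seed}.
#' @param comparisons list of \code{c(case, control)} pairs to run.
#' @param minFreq,hweAlpha allele filter settings.
#' @param haplotypeArities arities for the class I haplotype scan.
#' @param seed integer seed for the mock predictor.
#' @param outDir output directory for the report bundle.
#' @return A validated \code{RunConfig} list.
#' @export
runConfig <- function(genotypes, sequences = NULL, ranks = NULL,
                      comparisons = list(c("CALR", "CONTROL"),
                                         c("CALR", "JAK2")),
                      minFreq = 0.02, hweAlpha = 0.1,
                      haplotypeArities = 2L, seed = 1L, outDir) {
  files <- c(genotypes, sequences, unlist(ranks))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("validation error: missing input file(s): ",
         paste(missing, collapse = ", "))
  structure(list(genotypes = genotypes, sequences = sequences,
                 ranks = ranks, comparisons = comparisons,
                 minFreq = minFreq, hweAlpha = hweAlpha,
                 haplotypeArities = as.integer(haplotypeArities),
                 seed = as.integer(seed), outDir = outDir),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.writeTsv <- function(df, outDir, file) {
  p <- file.path(outDir, file)
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g")))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  p
}

#' Run the end-to-end study
#'
#' Executes the full analysis sequence on one or more genotype tables:
#' peptide enumeration for both built-in mutations, rank ingestion (or
#' the deterministic mock predictor), per-allele best ranks with
#' binder-category annotation, per-subject PHBRs, HED when sequences
#' are supplied, allele and category association for each configured
#' comparison, the class I haplotype scan, PHBR group comparisons and
#' the cross-mutation PHBR correlation. One TSV per analysis plus a
#' run manifest (seed, parameters, input checksums) is written to the
#' output directory; outputs are byte-identical across reruns of the
#' same configuration.
#'
#' @param config a \code{\link{runConfig}}.
#' @return Invisibly, a named list of output paths.
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  cohorts <- .stage("read_genotypes",
                    lapply(config$genotypes, readGenotypeTable))
  cohort <- if (length(cohorts) > 1L)
    .stage("pool", poolCohorts(cohorts)) else cohorts[[1L]]
  psets <- .stage("enumerate", list(
    CALRmut = enumerateNeoTerminus(calrNeoContext()),
    JAK2V617F = enumeratePointMutation(jak2V617FContext())))
  alleles <- cohortAlleles(cohort, HLA_CLASS_I)
  rankTables <- .stage("ranks", {
    if (!is.null(config$ranks)) {
      lapply(config$ranks, readRankTable)
    } else {
      lapply(psets, function(ps)
        mockRankPredictor(alleles, peptides(ps), config$seed))
    }
  })
  brTabs <- .stage("best_ranks", lapply(names(psets), function(m)
    cbind(alleleBestRanks(rankTables[[m]], alleles, psets[[m]]),
          category = NA)))
  names(brTabs) <- names(psets)
  for (m in names(brTabs))
    brTabs[[m]]$category <- as.character(categorizeBinder(brTabs[[m]]$br))
  outputs$best_ranks <- .writeTsv(do.call(rbind, brTabs), config$outDir,
                                  "best_ranks.tsv")
  phbrTab <- .stage("phbr", cohortPhbrTable(cohort, rankTables, psets))
  outputs$phbr <- .writeTsv(phbrTab, config$outDir, "phbr.tsv")
  if (!is.null(config$sequences)) {
    db <- .stage("sequences", readImgtProteinFasta(config$sequences))
    hed <- .stage("hed", cohortHed(cohort, db))
    outputs$hed <- .writeTsv(hed, config$outDir, "hed.tsv")
    cmpH <- .stage("hed_comparison",
                   hedGroupComparison(hed, cohort, "mean_class_I"))
    outputs$hed_comparison <- .writeTsv(
      cbind(cmpH$tests, measure = "mean_class_I"),
      config$outDir, "hed_comparison.tsv")
  }
  ann <- do.call(rbind, lapply(names(brTabs), function(m)
    data.frame(allele = brTabs[[m]]$allele, mutation_id = m,
               category = brTabs[[m]]$category)))
  for (cmp in config$comparisons) {
    tag <- paste0(tolower(cmp[1]), "_vs_", tolower(cmp[2]))
    res <- .stage(paste0("assoc_", tag),
                  associateAlleles(cohort, cmp[1], cmp[2],
                                   minFreq = config$minFreq,
                                   hweAlpha = config$hweAlpha))
    outputs[[paste0("alleles_", tag)]] <-
      .writeTsv(res, config$outDir, paste0("assoc_alleles_", tag, ".tsv"))
    outputs[[paste0("volcano_", tag)]] <-
      .writeTsv(renderVolcanoTable(res), config$outDir,
                paste0("volcano_alleles_", tag, ".tsv"))
    resc <- .stage(paste0("categories_", tag),
                   associateCategories(cohort, ann, cmp[1], cmp[2]))
    outputs[[paste0("categories_", tag)]] <-
      .writeTsv(resc, config$outDir,
                paste0("assoc_categories_", tag, ".tsv"))
    hap <- .stage(paste0("haplotypes_", tag),
                  haplotypeAssociationScan(cohort, "I",
                                           config$haplotypeArities,
                                           cmp[1], cmp[2]))
    outputs[[paste0("haplotypes_", tag)]] <-
      .writeTsv(hap, config$outDir,
                paste0("assoc_haplotypes_", tag, ".tsv"))
  }
  corr <- .stage("phbr_correlation", {
    s <- subjectTable(cohort)
    grp <- setNames(paste(s$cohort, s$group, sep = ":"), s$subject_id)
    phbrCorrelation(phbrTab, grp)
  })
  outputs$phbr_correlation <- .writeTsv(corr, config$outDir,
                                        "phbr_correlation.tsv")
  manifest <- data.frame(
    key = c("package_version", "seed", "min_freq", "hwe_alpha",
            paste0("md5_", basename(config$genotypes))),
    value = c(as.character(utils::packageVersion("hlaImmunoedit")),
              config$seed, config$minFreq, config$hweAlpha,
              unname(tools::md5sum(config$genotypes))))
  outputs$manifest <- .writeTsv(manifest, config$outDir, "manifest.tsv")
  invisible(outputs)
}

#' Volcano-ready view of an association table
#'
#' Keeps tested terms only and adds the \code{-log10(p)} and label
#' columns a volcano plot needs; plotting itself is left to the caller.
#'
#' @param res output of \code{\link{associateAlleles}} or
#'   \code{\link{associateCategories}}.
#' @param alpha significance line (default 0.05, unadjusted).
#' @return data.frame \code{label}, \code{log_or}, \code{neg_log10_p},
#'   \code{significant}.
#' @export
renderVolcanoTable <- function(res, alpha = 0.05) {
  res <- res[res$filter_status == "TESTED", , drop = FALSE]
  data.frame(label = res$term, log_or = res$log_or,
             neg_log10_p = -log10(res$p_wald),
             significant = !is.na(res$p_wald) & res$p_wald < alpha,
             row.names = NULL)
}
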