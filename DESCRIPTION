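Package: hlaImmunoedit
Title: HLA-Restricted Presentation of Myeloproliferative Neoplasm Driver
    Mutation Neoantigens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying immunogenetic restriction of the two major
    myeloproliferative neoplasm driver mutations (mutant CALR and JAK2
    V617F). Enumerates candidate neoantigen peptides from the neomorphic
    CALR C-terminus and from point substitutions, scores HLA class I
    genotypes for their predicted ability to present them (per-allele best
    rank, patient harmonic-mean best rank, strong/weak/non-binder
    annotation), quantifies HLA genotype diversity as evolutionary
    divergence via the Grantham distance, and runs case-control allele and
    haplotype association analyses with Hardy-Weinberg and frequency
    filtering, EM haplotype frequency estimation and score tests, pooled
    multi-cohort models, and cross-mutation presentation-score
    correlations. Includes a synthetic cohort generator with planted
    effects so every stage is testable without access to subject-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, Immunology, SNP, StatisticalMethod
RoxygenNote: 7.3.3
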