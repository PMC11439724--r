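# hlaImmunoedit

Immunogenetic restriction analysis for the two major myeloproliferative
neoplasm (MPN) driver mutations — frameshifting **CALR exon 9**
mutations (which create a shared neomorphic C-terminal protein
sequence) and the **JAK2 V617F** point substitution. If HLA class I
molecules present driver-derived neoantigens to T cells early in clonal
evolution, immune selection should skew patients' germline HLA
genotypes. This package implements the complete analytic chain used to
look for that skew, for researchers in cancer immunogenetics and
statistical genetics:

* **Neoantigen enumeration** — all 8–11-mer windows of the 44-residue
  neomorphic CALR C-terminus (142 windows) and all windows covering the
  V617F substitution (38 with full flanks); 15-mers for class II
  predictor input.
* **Presentation scoring** — per allele, the best rank
  `BR = min over mutant peptides of the predictor percentile rank`;
  per subject, the patient harmonic-mean best rank
  `PHBR = 6 / Σᵢ 1/BRᵢ` over the six class I allele copies (homozygotes
  counted twice); strong/weak/non-binder annotation at percentile ranks
  0.5 and 2.
* **HLA evolutionary divergence (HED)** — per locus, the mean Grantham
  distance between the two alleles' binding-groove sequences
  (`D(a,b) = ρ√(α Δc² + β Δp² + γ Δv²)`), zero for homozygotes, with
  class I/II means.
* **Case-control association** — additive logistic models per allele
  (dosage 0/1/2) with age and sex covariates, gated by a ≥2% frequency
  filter and an exact Hardy–Weinberg equilibrium test (alleles with
  HWE p < 0.1 excluded); binder-category association without filters;
  EM haplotype frequency estimation from unphased genotypes with
  imputed-dosage score tests over bi-/tri-/quadruple-locus systems.
* **Meta-analysis tools** — multi-cohort pooling with fixed-effect
  cohort covariates, and the cross-mutation Pearson correlation between
  per-subject PHBRs for the two drivers.
* **A synthetic-cohort generator** — per-locus frequency spectra,
  haplotype-table linkage, an inbreeding (HWE-violation) knob,
  logistic phenotype assignment with planted allele log-odds-ratios,
  and rank tables with a planted allele-level BR correlation between
  mutations, so every stage is testable against known truth.

## Worked example

A synthetic study with a planted protective allele (log-OR −0.9 for
`A*90:01` in CALR cases) and a planted allele-level BR correlation of
−0.6 between the two mutations:

```r
library(hlaImmunoedit)

cfg <- simulationConfig(seed = 42,
                        groupSizes = c(CALR = 60L, JAK2 = 100L, CONTROL = 400L),
                        plantedLogOR = list(CALR = c("A*90:01" = -0.9)),
                        brCorrelation = -0.6)
cohort <- simulateCohort(cfg)
cohort
#> HlaCohort "sim": 560 subjects (CALR 60, JAK2 100, CONTROL 400)
#>   typed loci: A, B, C

psets <- list(CALRmut   = enumerateNeoTerminus(calrNeoContext()),
              JAK2V617F = enumeratePointMutation(jak2V617FContext()))
psets$CALRmut
#> PeptideSet CALRmut : 142 windows (k 8 - 11 ), 142 distinct peptides

rt   <- simulateRankTable(cohortAlleles(cohort), psets, cfg)
phbr <- cohortPhbrTable(cohort, lapply(rt, `[[`, "table"), psets)
head(phbr, 3)
#>   subject_id mutation_id      phbr n_alleles_used
#> 1   sim00003     CALRmut 0.2156881              6
#> 2   sim00019     CALRmut 0.1434069              6
#> 3   sim00024     CALRmut 0.2353232              6

res <- associateAlleles(cohort, "CALR", "CONTROL")
head(res[order(res$p_wald),
         c("term", "freq_case", "freq_control", "or_",
           "ci95_low", "ci95_high", "p_wald", "filter_status")], 3)
#>       term freq_case freq_control   or_ ci95_low ci95_high p_wald filter_status
#> 1  A*90:01    0.0333       0.1062 0.284    0.101     0.795 0.0165        TESTED
#> 9  A*90:11    0.0583       0.0238 3.017    1.187     7.670 0.0203        TESTED
#> 15 B*90:05    0.0750       0.0387 2.010    0.895     4.516 0.0909        TESTED
```

The planted allele surfaces with the smallest p-value and an odds-ratio
estimate (0.28, CI 0.10–0.80) bracketing the planted OR of
exp(−0.9) ≈ 0.41; its case frequency (3.3%) is depleted relative to
controls (10.6%) as planted. The planted inverse presentation trade-off
appears as negative per-group PHBR correlations:

```r
grp <- setNames(subjectTable(cohort)$group, subjectTable(cohort)$subject_id)
phbrCorrelation(phbr, grp)
#>     group   n      r        p
#> 1    CALR  60 -0.231 0.075594
#> 2 CONTROL 400 -0.164 0.000973
#> 3    JAK2 100 -0.240 0.016168
```

A negative r means genotypes that present CALR-neoterminus peptides
well (low PHBR) tend to present JAK2 V617F peptides poorly — the
restriction trade-off hypothesised to shape which driver mutation a
patient's nascent clone can sustain.

`runStudy(runConfig(...))` chains every stage (enumeration → ranks →
BR/PHBR/categories → HED → allele, category and haplotype association →
PHBR correlations) over genotype TSVs and writes one output TSV per
analysis plus a reproducibility manifest; `generateFixtureSuite()`
writes a complete miniature three-cohort study in all interchange
formats.

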