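---
title: "Methods: scoring HLA-restricted presentation of MPN driver-mutation neoantigens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring HLA-restricted presentation of MPN driver-mutation neoantigens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaImmunoedit)
```

# The scientific question

Myeloproliferative neoplasms (MPN) are driven almost mutually exclusively
by one of two somatic lesions: the JAK2 V617F point substitution or
frameshifting CALR exon 9 mutations that replace the C-terminus of
calreticulin with a shared novel ("neomorphic") arginine/methionine-rich
sequence. Both lesions create mutation-specific peptides absent from the
normal proteome. If HLA class I molecules present such neoantigens to
CD8+ T cells early in clonal evolution, immune selection
("immunoediting") should leave fingerprints in patients' germline HLA
genotypes: depletion of alleles that present the driver well, and an
inverse relationship between a genotype's capacity to present one
driver's neoantigens versus the other's.

This package implements the full analytic chain needed to look for those
fingerprints: neoantigen enumeration, genotype-level presentation
scoring, genotype diversity scoring, and case-control association at the
allele, binder-category and haplotype level — plus a synthetic-cohort
generator so that every stage can be validated against planted truth
without access to subject-level patient data.

# Peptide enumeration

Class I neoantigen candidates are all 8-11-mers (octamers through
endecamers). Two enumeration modes exist because the two driver
mutations create neoantigens differently:

* **Neo-terminus mode** (CALR): the entire novel C-terminal segment is
  mutant, so every window of every length is a candidate. For the
  44-residue neomorphic CALR C-terminus this gives
  $\sum_{k=8}^{11}(44-k+1) = 142$ windows.
* **Point-substitution mode** (JAK2 V617F): only windows covering the
  substituted residue are mutant. With at least 10 flanking residues on
  both sides this gives $\sum_{k=8}^{11} k = 38$ windows, clipped near
  sequence ends otherwise.

Counts are *positional*: a peptide string occurring at two distinct
starts is counted twice, so the sliding-window arithmetic above is the
canonical count. Deduplicated peptide strings are what goes to the
binding predictor (`peptides()`).

The CALR neo-terminus ships as a built-in constant. The JAK2 context
ships as the canonical JAK2 segment spanning residues 607-627 with
phenylalanine substituted at 617; any user-supplied context with full
flanks reproduces the same window count, and the built-in one yields the
two JAK2-derived nonamers (LVLNYGVCF, VLNYGVCFC) studied experimentally
in this field. Class II prediction input uses 15-mer windows
(`enumerateClassII()`); class II presentation scores are deliberately
not computed (predictor conventions differ and the class I score is the
object of study).

# Presentation scoring: BR and PHBR

External neural-network predictors assign each (allele, peptide) pair a
*percentile rank* (percent of random natural peptides predicted to bind
better; lower = better presented). The package consumes such tables —
either its simple TSV interchange or the predictor's multi-allele tab
export — and never reimplements the predictor itself. For testing and
simulation a deterministic *mock* predictor is provided that hashes
(allele, peptide, seed) to a rank, so tables are bit-reproducible across
platforms with no RNG involvement.

Per allele and mutation, the **best rank (BR)** is the minimum rank over
the mutation's (deduplicated) peptide set: the allele's single best shot
at presenting any mutant window. Missing predictions fail loudly by
default; an explicit `missingRank` argument exists for robustness
experiments only.

Per subject, the **patient harmonic-mean best rank (PHBR)** is the
harmonic mean of the six class I allele BRs (both alleles of A, B, C; a
homozygous allele's BR is counted twice):
$\mathrm{PHBR} = 6 / \sum_{i=1}^{6} 1/\mathrm{BR}_i$.
The harmonic mean is dominated by its smallest term, so a genotype with
even one strongly presenting allele scores low (= good presentation).
One interpretive decision deserves emphasis: "best rank per locus"
phrasing in the field is resolved here as *BR per allele*, with the
six-allele harmonic mean as the subject score — the construction of the
PHBR literature. Subjects with an incomplete class I genotype are
skipped and reported, never imputed.

Alleles are annotated per mutation with the predictor's standard
thresholds: strong binder (SB) at BR ≤ 0.5, weak binder (WB) at
0.5 < BR ≤ 2, non-binder (NB) above, boundaries inclusive on the
lower-category side (matching the predictor's own labelling).

# HLA evolutionary divergence (HED)

HED measures how structurally different a locus's two alleles are: the
mean Grantham distance over aligned positions of the two binding-groove
sequences, zero for homozygotes. More divergent allele pairs can jointly
present a broader peptide repertoire. Class I and class II means average
the three (A, B, C) and four (DPB1, DQA1, DQB1, DRB1) locus HEDs, and a
class mean is only reported when all constituent loci are evaluable.

The Grantham distance combines side-chain composition, polarity and
volume differences:
$D(a,b) = \rho\sqrt{\alpha(c_a-c_b)^2 + \beta(p_a-p_b)^2 + \gamma(v_a-v_b)^2}$
with the 1974 constants ($\alpha$ = 1.833, $\beta$ = 0.1018, $\gamma$ =
0.000399, $\rho$ = 50.723). The shipped integer matrix is canonical for
all computations; the closed-form formula with the published residue
property values is retained as an independent validation oracle
(`granthamDistanceFormula()`). A handful of historically printed matrix
entries differ by one unit from exact recomputation, so the matrix file
declares a rounding tolerance of 1 and the validation asserts agreement
within it.

Binding-groove extraction ranges are configuration values
(`readImgtProteinFasta(domainRanges=)`): the class I
$\alpha_1+\alpha_2$ segment and class II membrane-distal domain
boundaries vary slightly between reference pipelines and are not
standardised, so the package documents them as user-set rather than
hard-coding one convention. Per two-field allele the first full-length
IMGT record is kept (reference-allele convention); allele pairs with
unequal extracted lengths are excluded with a warning rather than
aligned on the fly.

# Case-control association

## Allele level

For each locus independently, each allele is coded additively (0/1/2
copies) and tested with a logistic model
$\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \beta_d\,\mathrm{dosage} +
\beta_{\mathrm{age}}\,\mathrm{age} + \beta_{\mathrm{sex}}\,\mathrm{sex}$,
reporting the Wald z-test on $\beta_d$ with a 95% CI. Before fitting,
two gates apply: overall frequency at least 2%, and an exact
Hardy-Weinberg test p ≥ 0.1 — read as *excluding* alleles with
significant HWE deviation at α = 0.1, the standard QC direction. HWE is
tested in controls by default (configurable), by collapsing each allele
against all other alleles of its locus pooled. Exclusions carry their
reason (`EXCLUDED_FREQ`, `EXCLUDED_HWE`); separation or non-convergence
yields `NOT_CONVERGED` with no estimates. Significance is read at
unadjusted p < 0.05 with a Benjamini-Hochberg column provided for
reference, matching the source analysis convention. Missing age or sex
drops a subject from that model only.

The HWE exact test enumerates every heterozygote count consistent with
the observed allele counts under the conditional (Levene-Haldane)
distribution and sums the probabilities of configurations no more
probable than the observed one, using the stable ratio recurrence
$P(n_{AB}+2)/P(n_{AB}) = 4n_{AA}n_{BB}/((n_{AB}+2)(n_{AB}+1))$.

## Binder-category level

The complementary analysis replaces allele identity with function: each
subject's six class I allele copies are counted into SB/WB/NB categories
per mutation (a 0-6 dosage per category term), and the same GLM is fit
with *no* frequency or HWE exclusion. Zero-variance terms (e.g. every
allele NB) are flagged untestable.

## Haplotype level

Multi-locus haplotype frequencies are estimated from unphased genotypes
by EM under random mating: the E-step distributes each subject over the
diplotypes consistent with their genotype in proportion to haplotype
frequency products, the M-step re-estimates frequencies from expected
counts. Initialisation at products of marginal allele frequencies is
deterministic and resolves likelihood ties (all-double-heterozygote
pathologies); the log-likelihood is non-decreasing by construction and
the stopping rule is a change below 1e-8. Haplotypes below 1e-6
frequency are pruned from the report.

Association uses the imputed-haplotype score construction: with the
null logistic model (covariates only) fitted once, each retained
haplotype's posterior expected dosage $d_i$ is scored by
$U = \sum_i d_i(y_i - \hat p_i)$ with variance
$V = d^{\top}Wd - d^{\top}WX(X^{\top}WX)^{-1}X^{\top}Wd$, giving a
signed z and a one-step effect estimate $U/V$ — no per-haplotype refit.
This matches the classical score-test construction for imputed
haplotype dosages; exact small-sample behaviour of other
implementations (permutation options, skewness corrections) is not
replicated. Haplotypes below 1% estimated frequency are not tested,
since only non-rare haplotypes are scientifically reportable at these
cohort sizes. The scan runs every locus combination of the requested
arities within a class (class I pairs: 3 combinations; the class II
quadruple: 1), dropping subjects missing any scan locus per combination
only.

## Pooled analysis and PHBR correlation

Multi-cohort pooling concatenates cohorts with their label preserved and
enters the label as fixed-effect indicators in one GLM, so
between-cohort frequency differences cannot masquerade as case-control
effects (demonstrated by a constructed-confounding test). With a single
cohort the indicator drops and results equal the unpooled fit;
per-cohort stratified estimates are attached for transparency. No
random-effects meta-analysis is attempted — at these cohort counts a
fixed-effect pooled model is the defensible choice.

The cross-mutation analysis computes, per subject group, the Pearson
correlation between PHBR for the CALR neo-terminus and PHBR for JAK2
V617F with a two-sided t-transform p. Correlations are computed on raw
PHBR values by default (a log10 option exists); Pearson r is invariant
to common rescaling, which is tested.

# The synthetic-data generator

The generator emulates exactly the statistical structure the analyses
assume, with planted truth recorded so recovery can be checked
mechanically:

* **Allele frequencies**: explicit per-locus spectra, or symmetric
  Dirichlet draws (default 12 alleles, concentration 0.5 — a few common
  and many rare alleles, the shape of real HLA loci). Synthetic alleles
  use a `*90:xx` numbering series to stay clear of real catalogues.
* **Linkage**: an optional haplotype frequency table over a locus
  subset; haplotypes are drawn jointly there, independently elsewhere.
* **HWE violation knob**: an inbreeding coefficient f — per locus the
  second allele copies the first with probability f, producing the
  heterozygote deficit the HWE gate is designed to catch.
* **Phenotypes**: two logistic disease models (CALR, JAK2) with planted
  per-allele log-odds-ratios plus age (+0.02/year) and male-sex (+0.2)
  terms; ages are normal (mean 60, SD 15) truncated to [18, 95],
  reflecting MPN's late-life incidence. Subjects are assigned by
  rejection: a subject enters the case group with its model probability,
  otherwise the other case group with its probability, otherwise the
  control pool — case sampling proportional to $p$ and control sampling
  proportional to $1-p$ preserves planted odds ratios in retrospective
  fits, which the parameter-recovery tests confirm.
* **Rank model**: per allele a latent bivariate normal with correlation
  $\rho$ maps to log-uniform BR ranges per mutation (defaults 0.05-40
  for the CALR neo-terminus, 0.5-80 for JAK2 V617F, encoding the
  empirical observation that CALR presentation scores run lower);
  peptide-level ranks are filled so the minimum over each mutation's
  peptides equals the drawn BR exactly. Negative $\rho$ plants the
  inverse cross-mutation correlation at the allele level — PHBR depends
  on ranks only through allele BRs, so that is the right level to
  plant at.

What the generator does **not** emulate: real HLA frequency atlases,
linkage beyond the supplied haplotype table, genotyping error or
ambiguity, population stratification within a cohort, and any
peptide-level biochemistry in the mock ranks. Passing tests therefore
demonstrate statistical correctness of the machinery, not biological
conclusions about real cohorts.

# Numerical and design choices

* Two-field allele resolution is the universe of analysis; higher
  resolution is truncated at ingest and expression suffixes are
  stripped with a per-allele flag.
* A locus with exactly one missing allele is dropped for that subject —
  keeping the lone allele would fabricate homozygosity in both PHBR and
  HED.
* Binder-category boundaries are inclusive (BR = 0.5 is SB, BR = 2.0 is
  WB).
* Separation in the GLM is detected by non-convergence or an exploding
  dosage coefficient/SE and reported as `NOT_CONVERGED`, never as an
  estimate.
* The EM expansion of a subject's diplotypes is capped (default 4096)
  to bound memory on pathological inputs.
* All pipeline randomness funnels through one seed; the mock predictor
  uses integer hashing so its output is bit-stable across platforms
  independently of R's RNG.

# Validation problem sizes

The test suite validates each stage at sizes chosen to give tight
Monte-Carlo resolution while remaining quick to run: the HWE
implementation-versus-oracle sweep covers every genotype configuration
up to 200 subjects; null calibration of the allele association uses
2,000 replicates of a balanced 300-case/300-control design at one
locus; planted-OR recovery uses 200 replicates of 400 cases/1,000
controls with the planted allele at 10% frequency; the planted inverse
BR correlation (-0.6) is checked over 50 seeded runs of 200 subjects;
the end-to-end pipeline determinism check runs the miniature
three-cohort fixture study twice and compares bytes.

# Known limitations

* The binder predictor is consumed, not reproduced; all results are
  conditional on the supplied rank tables.
* The haplotype score test's small-sample refinements (permutation
  p-values, skewness corrections) are not implemented.
* Class II PHBR is intentionally absent.
* HED depends on the user-supplied binding-groove ranges; shipped
  defaults are documented conventions, not IMGT-mandated constants.
* The Wald test in the additive GLM is slightly conservative at small
  carrier counts, a well-known finite-sample property visible in the
  null-calibration numbers.
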