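# acrotype

Genomic and transcriptomic subtyping of acral melanoma cohorts.

Acral melanoma — melanoma of the glabrous skin of the palms, soles and
nail unit — is not ultraviolet-driven, carries far fewer mutations in the
classical drivers (*BRAF*, *NRAS*, *NF1*, *KIT*) than cutaneous melanoma,
and predominates in many non-European-ancestry populations that remain
under-represented in cancer genomics. Analysing such cohorts requires a
specific chain of computations that this package implements as tested,
reusable components:

- **Variant consensus** — merge somatic calls from three callers, keeping
  sites seen by at least two of the three, with a protein-change rescue
  list (by default *BRAF* p.V600E survives single-caller support), Phred
  base-quality ≥ 30 filtering, strand-bias removal, one-sample-per-patient
  selection (primaries preferred), driver classification
  (*BRAF*/*NRAS*/*KIT*/*NF1*/multi-hit/QWT, where QWT = quadruple wild
  type) and tumour mutational burden (TMB, SNVs + indels per Mb).
- **Copy number** — purity/ploidy QC of paired estimators, segment means
  `log2(cn/ψ)`, GISTIC-style region classification (±0.25 / 0.9 / −1.3
  cuts), broad/focal/global burden scores (BCS, FCS, GCS = min–max
  normalized sum), and homozygous-deletion calling from bin-level log2
  ratios against the purity/ploidy-specific threshold
  `log2(2(1−ρ)/(ρψ+2(1−ρ)))`, with separate rules for large genes
  (*NF1*-like: two contiguous bins at/below threshold, or a zero-coverage
  exon) and small genes (*CDKN2A*-like: one bin below, two near, and a
  clear drop versus flanking bins).
- **Melanocytic-origin score** — the multiplicative acral:cutaneous (A:C)
  score: housekeeping geometric-mean normalization with a background
  floor of 20, PCA on the log2 matrix, selection of the label-associated
  component, top/bottom-10 loading genes as the two panel sides, and the
  ratio of the products of the log2 expression values; higher = more
  acral-like (v-type melanocyte program).
- **Consensus clustering** — matrix preprocessing (NA filtering,
  winsorization, variance filtering), subsampled consensus partitioning
  (sd/mad/cv features × kmeans/pam/hclust), stability metrics (1-PAC,
  concordance, Jaccard, silhouette), F-test signature genes with BH
  correction, k-means gene modules over scaled cluster profiles, and
  hypergeometric over-representation analysis.
- **Statistics** — self-contained Pearson χ² (no continuity correction),
  exact Fisher 2×2 and Freeman–Halton r×c tests by enumeration,
  Wilcoxon–Mann–Whitney with exact small-sample p values, Pearson
  correlation, logistic regression by IRLS with Wald intervals, BH FDR,
  Kaplan–Meier with Greenwood variance and log-log bands, the log-rank
  test, and Cox proportional hazards with Efron ties and optional
  delayed entry. Each is verified against an independent oracle in the
  test suite.
- **Synthetic cohorts** — a generator that plants every effect the
  analyses are meant to find (Dirichlet admixture ancestry, ancestry- and
  sex-dependent drivers, two-lineage negative-binomial expression with
  three cluster modules and a BRAF shift toward the cutaneous program,
  purity/ploidy-contaminated copy number with homozygous deletions,
  logistic recurrence and proportional-hazards survival), so the whole
  pipeline is testable without controlled-access patient data.

## Worked example

```r
library(acrotype)

co   <- simulateCohort(defaultSimConfig(nPatients = 44), seed = 7)
cons <- mergeCallers(filterQuality(cohortVariants(co)))
cl   <- cohortClinical(co)
prof <- driverProfiles(cons, data.frame(patient = cl$patient,
          sample = paste0(cl$patient, "-T1"), type = "primary"))
table(prof$category)
#>      BRAF       KIT multi-hit       NF1      NRAS       QWT
#>         3         4         1         3         3        30
mean(prof$tmb)
#> [1] 1.069  # mutations per megabase

norm <- normalizeCounts(round(SummarizedExperiment::assay(
          cohortExpression(co), "counts")), sprintf("HK%02d", 1:10))
cc <- consensusPartition(preprocessMatrix(norm$log2), kRange = 2:5,
                         nResamples = 30, seed = 11)
cc
#> ConsensusResult: sd : pam  chosen k = 3
#>  k    onePAC meanSilhouette concordance jaccardPrevK
#>  2 0.3858351      0.6418503   0.7271429           NA
#>  3 1.0000000      1.0000000   1.0000000    0.5346715
#>  4 0.9344609      0.9585785   0.9817460    0.8476190
#>  5 0.9133192      0.9140250   0.9722751    0.8518519

logisticFit(cbind(mutated = cl$mutated, age = cl$age), cl$recurrence)
#> Logistic regression (IRLS), n = 44
#>                    beta         se        OR        lo95      hi95        p
#> (Intercept) -1.45848190 1.74123056 0.2325891 0.007663925  7.058745 0.402247
#> mutated      1.94081763 0.87310960 6.9644430 1.258039119 38.554816 0.026224
#> age          0.02332816 0.02720043 1.0236024 0.970461354  1.079653 0.391092
```

The consensus table says the 44 samples partition into three perfectly
stable transcriptional clusters (1-PAC = 1 at k = 3, lower at every other
k), recovering the three planted expression modules; the logistic fit
estimates the recurrence odds ratio for driver-mutated tumours in this
small simulated cohort (planted value 5.31, here estimated 6.96 with a
wide Wald interval — small-cohort behaviour the package is designed to
expose).

`referenceChecks()` re-computes four contingency tests on tables embedded
from published cohort summaries (no input files needed), e.g. the
recurrence-by-driver 2×2 gives χ² = 7.38, p = 0.0066.

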