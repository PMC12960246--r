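Package: acrotype
Title: Genomic and Transcriptomic Subtyping of Acral Melanoma Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cohort-scale genomic and transcriptomic subtyping of
    acral melanoma. Implements a multi-caller somatic variant consensus with
    driver-gene classification and tumour mutational burden, purity- and
    ploidy-aware copy-number burden scores and homozygous-deletion calling
    from bin-level log2 ratios, a melanocytic-origin (acral:cutaneous) gene
    expression score trained by principal component analysis, consensus
    clustering with stability-based model selection and two-level gene
    signature analysis, and the supporting statistical inference (exact and
    asymptotic contingency tests, rank tests, logistic regression,
    Kaplan-Meier, log-rank and Cox proportional hazards). A synthetic-cohort
    generator with planted ground truth makes every stage testable without
    access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    DESeq2,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    survival,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
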