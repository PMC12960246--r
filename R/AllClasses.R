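#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' SyntheticCohort: a simulated acral-melanoma cohort with planted truth
#'
#' Bundles every data layer a cohort analysis consumes: a count-level
#' expression experiment (with per-sample origin class, transcriptional
#' cluster and BRAF status in `colData`), per-caller somatic variant calls,
#' allele-specific copy-number segments, bin-level log2 ratios, per-sample
#' purity/ploidy estimates, and a per-patient clinical table. The `truth`
#' list records every planted parameter and label so downstream stages can
#' be scored against ground truth.
#'
#' @slot expression A [SummarizedExperiment::SummarizedExperiment] with a
#'   `counts` assay (genes x samples).
#' @slot variants data.frame of per-sample, per-caller calls.
#' @slot segments data.frame of copy-number segments (1-based inclusive).
#' @slot bins data.frame of bin-level log2 ratios (0-based half-open).
#' @slot purityPloidy data.frame with two purity estimates, ploidy,
#'   goodness of fit and a WGD flag per sample.
#' @slot clinical data.frame, one row per patient.
#' @slot truth list of planted parameters and labels.
#' @export
setClass("SyntheticCohort",
  representation(expression = "SummarizedExperiment",
                 variants = "data.frame",
                 segments = "data.frame",
                 bins = "data.frame",
                 purityPloidy = "data.frame",
                 clinical = "data.frame",
                 truth = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character(0)
  cl <- object@clinical
  if (nrow(cl)) {
    anc <- as.matrix(cl[, c("amr", "eur", "afr")])
    if (any(abs(rowSums(anc) - 1) > 1e-9))
      msg <- c(msg, "ancestry fractions must sum to 1 within 1e-9")
    for (col in intersect(c("timeRecurrence", "timeDeath"), names(cl)))
      if (any(cl[[col]] < 0, na.rm = TRUE))
        msg <- c(msg, paste0("negative times in ", col))
  }
  ids <- colnames(object@expression)
  pats <- object@clinical$patient
  for (nm in c("variants", "segments", "purityPloidy")) {
    df <- slot(object, nm)
    if (nrow(df) && (length(ids) || length(pats)) &&
        !all(df$sample %in% ids | sub("-.*", "", df$sample) %in% pats))
      msg <- c(msg, paste0("unknown sample identifiers in ", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticCohort Compact display.
#' @param object A `SyntheticCohort`.
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", ncol(object@expression), "samples,",
      nrow(object@expression), "genes,", nrow(object@clinical),
      "patients\n")
  cat("  variants:", nrow(object@variants), "caller records;",
      "segments:", nrow(object@segments), ";",
      "bins:", nrow(object@bins), "\n")
  cat("  truth components:", paste(names(object@truth), collapse = ", "),
      "\n")
})

#' @rdname SyntheticCohort
#' @export
cohortExpression <- function(object) object@expression
#' @rdname SyntheticCohort
#' @export
cohortVariants <- function(object) object@variants
#' @rdname SyntheticCohort
#' @export
cohortSegments <- function(object) object@segments
#' @rdname SyntheticCohort
#' @export
cohortBins <- function(object) object@bins
#' @rdname SyntheticCohort
#' @export
cohortPurityPloidy <- function(object) object@purityPloidy
#' @rdname SyntheticCohort
#' @export
cohortClinical <- function(object) object@clinical
#' @rdname SyntheticCohort
#' @export
cohortTruth <- function(object) object@truth

#' ScorePanel: trained acral/cutaneous gene panel
#'
#' The gene panel behind the melanocytic-origin (A:C) score: `nGenes`
#' acral-program genes, `nGenes` cutaneous-program genes, the loadings of
#' the class-separating principal component, and training metadata.
#'
#' @slot acralGenes,cutaneousGenes Character vectors (disjoint, equal
#'   length).
#' @slot loadings Named numeric vector of loadings for the panel genes.
#' @slot component Integer index of the selected principal component.
#' @slot training list (sample counts per class, label correlation).
#' @export
setClass("ScorePanel",
  representation(acralGenes = "character", cutaneousGenes = "character",
                 loadings = "numeric", component = "integer",
                 training = "list"))

setValidity("ScorePanel", function(object) {
  msg <- character(0)
  if (length(intersect(object@acralGenes, object@cutaneousGenes)))
    msg <- c(msg, "acral and cutaneous gene lists must be disjoint")
  if (length(object@acralGenes) != length(object@cutaneousGenes))
    msg <- c(msg, "panel sides must have equal size")
  ld <- object@loadings
  if (length(ld)) {
    sa <- sign(ld[object@acralGenes]); sc <- sign(ld[object@cutaneousGenes])
    if (length(unique(sa)) > 1 || length(unique(sc)) > 1 ||
        any(sa == sc[1]))
      msg <- c(msg, "loadings must be sign-consistent with panel sides")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ScorePanel Compact display.
#' @param object A `ScorePanel`.
#' @export
setMethod("show", "ScorePanel", function(object) {
  cat("ScorePanel: component", object@component, "\n")
  cat("  acral:    ", paste(object@acralGenes, collapse = " "), "\n")
  cat("  cutaneous:", paste(object@cutaneousGenes, collapse = " "), "\n")
})

#' @rdname ScorePanel
#' @export
acralGenes <- function(object) object@acralGenes
#' @rdname ScorePanel
#' @export
cutaneousGenes <- function(object) object@cutaneousGenes
#' @rdname ScorePanel
#' @export
panelLoadings <- function(object) object@loadings
#' @rdname ScorePanel
#' @export
panelComponent <- function(object) object@component

#' ConsensusResult: consensus clustering output
#'
#' Holds, for each candidate number of clusters k, the sample-by-sample
#' consensus matrix and stability metrics (1-PAC, mean silhouette,
#' concordance, Jaccard against k - 1), plus the chosen configuration and
#' final sample labels.
#'
#' @slot consensus list of consensus matrices, one per k (named "2", "3"...).
#' @slot metrics data.frame with one row per k.
#' @slot labels list of integer label vectors per k.
#' @slot chosen list: `featureMethod`, `baseMethod`, `k`.
#' @export
setClass("ConsensusResult",
  representation(consensus = "list", metrics = "data.frame",
                 labels = "list", chosen = "list"))

setValidity("ConsensusResult", function(object) {
  msg <- character(0)
  for (M in object@consensus) {
    if (max(abs(M - t(M))) > 1e-9)
      msg <- c(msg, "consensus matrix must be symmetric")
    if (any(M < -1e-9 | M > 1 + 1e-9))
      msg <- c(msg, "consensus entries must lie in [0, 1]")
    if (any(abs(diag(M) - 1) > 1e-9))
      msg <- c(msg, "consensus diagonal must be 1")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn ConsensusResult Compact display.
#' @param object A `ConsensusResult`.
#' @export
setMethod("show", "ConsensusResult", function(object) {
  ch <- object@chosen
  cat("ConsensusResult:", ch$featureMethod, ":", ch$baseMethod,
      " chosen k =", ch$k, "\n")
  print(object@metrics, row.names = FALSE)
})

#' @rdname ConsensusResult
#' @export
consensusMatrix <- function(object, k = NULL) {
  k <- k %||% object@chosen$k
  object@consensus[[as.character(k)]]
}
#' @rdname ConsensusResult
#' @param object A `ConsensusResult`.
#' @param k Number of clusters (defaults to the chosen k).
#' @export
clusterLabels <- function(object, k = NULL) {
  k <- k %||% object@chosen$k
  object@labels[[as.character(k)]]
}
#' @rdname ConsensusResult
#' @export
stabilityMetrics <- function(object) object@metrics
#' @rdname ConsensusResult
#' @export
chosenPartition <- function(object) object@chosen

#' GeneModuleSet: k-means gene modules over cluster profiles
#'
#' Partition of the signature genes into modules (M1, M2, ...) by k-means
#' on their row-standardized mean expression profiles across sample
#' clusters. Modules are labelled by the sample cluster in which their mean
#' profile peaks.
#'
#' @slot modules data.frame with columns `gene` and `module`.
#' @slot profiles matrix: module x sample-cluster scaled mean profiles.
#' @export
setClass("GeneModuleSet",
  representation(modules = "data.frame", profiles = "matrix"))

setValidity("GeneModuleSet", function(object) {
  msg <- character(0)
  pr <- object@profiles
  if (nrow(pr)) {
    if (any(abs(rowMeans(pr)) > 1e-9))
      msg <- c(msg, "profiles must be row-centred")
    sds <- apply(pr, 1, stats::sd)
    if (any(abs(sds - 1) > 1e-6 & sds > 0))
      msg <- c(msg, "profiles must be row-standardized")
  }
  if (anyDuplicated(object@modules$gene))
    msg <- c(msg, "modules must partition the signature genes")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModuleSet Compact display.
#' @param object A `GeneModuleSet`.
#' @export
setMethod("show", "GeneModuleSet", function(object) {
  cat("GeneModuleSet:", nrow(object@modules), "genes in",
      nrow(object@profiles), "modules\n")
  print(table(object@modules$module))
})

#' @rdname GeneModuleSet
#' @export
moduleMembers <- function(object) object@modules
#' @rdname GeneModuleSet
#' @export
moduleProfiles <- function(object) object@profiles
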