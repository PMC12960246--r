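## The melanocytic-origin (acral:cutaneous, "A:C") score: normalization of
## counting-panel or RNA-seq data, PCA-based panel training, and the
## multiplicative score with its rank-test comparisons.
##
## The score is a ratio of products of floored log2 expression values over
## the two panel sides. The background floor (> 1 on the log2 scale after
## flooring raw counts, or an explicit 1 + 2^-10 floor for RNA-seq) keeps
## every factor positive, so the score is finite and positive; a log-score
## (sum of log2 of the log2 values) is exposed for numerical stability.

#' Normalize counting-panel expression by housekeeping geometric means
#'
#' Each sample is scaled by (cohort reference) / (sample housekeeping
#' geometric mean), where the reference is the geometric mean of the
#' per-sample housekeeping geometric means. Counts are then floored at the
#' background threshold (default 20) and log2 transformed, so every value
#' used by downstream scoring exceeds log2(20) > 4.
#'
#' @param raw Non-negative count matrix, genes x samples.
#' @param housekeeping Character vector of housekeeping gene ids (rows of
#'   `raw`).
#' @param background Background floor on the count scale (default 20).
#' @param reference Optional fixed reference value for the scale factors
#'   (e.g. carried over from a training cohort); defaults to the geometric
#'   mean of this cohort's housekeeping geometric means. With a fixed
#'   reference, a sample-wide multiplicative factor on the raw counts
#'   cancels exactly.
#' @return list with `log2` (the normalized, floored, log2 matrix),
#'   `factors` (per-sample scale factors), `floor` (log2 of `background`)
#'   and `housekeeping`.
#' @export
normalizeCounts <- function(raw, housekeeping, background = 20,
                            reference = NULL) {
  if (!all(housekeeping %in% rownames(raw)))
    stop("housekeeping genes absent from matrix: ",
         paste(setdiff(housekeeping, rownames(raw)), collapse = ", "),
         call. = FALSE)
  if (any(raw < 0)) stop("counts must be non-negative", call. = FALSE)
  hk <- raw[housekeeping, , drop = FALSE]
  zero <- which(hk == 0, arr.ind = TRUE)
  if (nrow(zero))
    stop("housekeeping gene with zero count: ",
         rownames(hk)[zero[1, 1]], " in sample ",
         colnames(hk)[zero[1, 2]], call. = FALSE)
  geomeans <- exp(colMeans(log(hk)))
  if (is.null(reference)) reference <- exp(mean(log(geomeans)))
  factors <- reference / geomeans
  scaled <- sweep(raw, 2, factors, `*`)
  floored <- pmax(scaled, background)
  list(log2 = log2(floored), factors = factors, reference = reference,
       floor = log2(background), housekeeping = housekeeping,
       transform = "log2-counts")
}

#' Normalize RNA-seq counts for origin scoring
#'
#' Median-of-ratios size-factor normalization (as used by standard
#' differential-expression tools), log2(x + 1) transform, optional
#' per-batch gene centring (batch means are removed and the overall gene
#' mean restored), and a final floor at `1 + 2^-10` on the log2 scale so
#' panel scoring only ever sees values above 1.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param batch Optional per-sample batch labels; with a single batch the
#'   centring step is the identity.
#' @param floorValue Log2-scale floor (default `1 + 2^-10`).
#' @return list with `log2`, `sizeFactors`, `floor`.
#' @export
normalizeRnaseq <- function(counts, batch = NULL,
                            floorValue = 1 + 2^-10) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  mat <- log2(sweep(counts, 2, sf, `/`) + 1)
  if (!is.null(batch)) {
    batch <- as.factor(batch)
    if (nlevels(batch) > 1) {
      if (any(table(batch) < 2))
        stop("batch with a single sample; cannot centre", call. = FALSE)
      overall <- rowMeans(mat)
      for (b in levels(batch)) {
        idx <- which(batch == b)
        mat[, idx] <- mat[, idx] - rowMeans(mat[, idx, drop = FALSE]) +
          overall
      }
    }
  }
  mat <- pmax(mat, floorValue)
  list(log2 = mat, sizeFactors = sf, floor = floorValue,
       transform = "log2-TPM+1")
}

#' Train the acral/cutaneous origin-score panel
#'
#' PCA of the log2 expression matrix with samples as observations and
#' genes as variables (column-centred, unscaled). The component whose
#' sample scores are most associated with the acral/cutaneous label
#' (largest |point-biserial correlation|) is selected and its index
#' reported; the top `nGenes` and bottom `nGenes` genes by loading form
#' the two panel sides. Orientation is fixed so that acral samples score
#' high: the positive-loading side is the acral side.
#'
#' @param log2mat Normalized log2 expression matrix, genes x samples.
#' @param labels Per-sample factor/character with levels `acral` and
#'   `cutaneous`.
#' @param nGenes Genes per panel side (default 10).
#' @return A [ScorePanel-class] object.
#' @export
trainPanel <- function(log2mat, labels, nGenes = 10) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("acral", "cutaneous")),
            length(labels) == ncol(log2mat))
  if (min(table(labels)) < 2)
    stop("need at least 2 samples per class", call. = FALSE)
  if (nrow(log2mat) < 2 * nGenes)
    stop("fewer candidate genes than 2 * nGenes", call. = FALSE)
  if (all(apply(log2mat, 1, stats::sd) == 0))
    stop("degenerate (zero-variance) matrix", call. = FALSE)
  pc <- stats::prcomp(t(log2mat), center = TRUE, scale. = FALSE)
  yb <- as.numeric(labels == "acral")
  usable <- which(pc$sdev > 1e-12)
  assoc <- vapply(usable, function(j)
    abs(suppressWarnings(stats::cor(pc$x[, j], yb))), numeric(1))
  comp <- usable[which.max(assoc)]
  loadings <- pc$rotation[, comp]
  scores <- pc$x[, comp]
  ## orient so acral samples have positive scores
  if (mean(scores[yb == 1]) < mean(scores[yb == 0])) {
    loadings <- -loadings; scores <- -scores
  }
  ord <- order(loadings, decreasing = TRUE)
  acral <- rownames(log2mat)[ord[seq_len(nGenes)]]
  cutaneous <- rownames(log2mat)[rev(ord)[seq_len(nGenes)]]
  panelGenes <- c(acral, cutaneous)
  new("ScorePanel", acralGenes = acral, cutaneousGenes = cutaneous,
      loadings = loadings[panelGenes], component = as.integer(comp),
      training = list(nAcral = sum(yb), nCutaneous = sum(1 - yb),
                      labelCorrelation = max(assoc)))
}

#' Product of log2 expression values over a gene list
#'
#' The multiplicative building block of the A:C score: the product of the
#' (floored) log2 expression values of `genes` in one sample. The empty
#' gene list yields 1 (empty product).
#'
#' @param sampleValues Named numeric vector: one sample's log2 expression.
#' @param genes Character vector of gene ids.
#' @return A single number.
#' @export
panelProduct <- function(sampleValues, genes) {
  if (!length(genes)) return(1)
  if (!all(genes %in% names(sampleValues)))
    stop("missing gene(s): ",
         paste(setdiff(genes, names(sampleValues)), collapse = ", "),
         call. = FALSE)
  prod(sampleValues[genes])
}

#' Acral:cutaneous origin score
#'
#' The multiplicative A:C score of each sample: the product of the
#' acral-side log2 expression values divided by the product of the
#' cutaneous-side values. With equal panel sides the score is invariant to
#' multiplying all log2 values by a constant. Higher scores are more
#' acral-like.
#'
#' @param log2mat Normalized log2 expression matrix (values > 1),
#'   genes x samples.
#' @param panel A [ScorePanel-class].
#' @return data.frame with columns `sample`, `score`, `logScore`
#'   (`log2(score)` computed as a difference of sums of `log2(log2 expr)`).
#' @export
acScore <- function(log2mat, panel) {
  genes <- c(acralGenes(panel), cutaneousGenes(panel))
  if (!all(genes %in% rownames(log2mat)))
    stop("panel gene(s) absent: ",
         paste(setdiff(genes, rownames(log2mat)), collapse = ", "),
         call. = FALSE)
  sub <- log2mat[genes, , drop = FALSE]
  stopifnot(all(sub > 0))  # guaranteed by the normalization floor
  la <- colSums(log2(sub[acralGenes(panel), , drop = FALSE]))
  lc <- colSums(log2(sub[cutaneousGenes(panel), , drop = FALSE]))
  logScore <- la - lc
  data.frame(sample = colnames(log2mat), score = 2^logScore,
             logScore = logScore, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Compare A:C scores between two groups
#'
#' Wilcoxon-Mann-Whitney comparison of scores between the two levels of
#' `grouping`. For one-sided tests, `alternative = "less"` tests that the
#' first group tends to score lower (e.g. BRAF-activating below wild type
#' on the A:C scale).
#'
#' @param scores data.frame from [acScore()] (or any with a `score`
#'   column).
#' @param grouping Two-level factor aligned with `scores`.
#' @param alternative Passed to [mannWhitney()]; direction refers to the
#'   first factor level.
#' @return An `acroTest` with group medians.
#' @export
compareScores <- function(scores, grouping,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  grouping <- as.factor(grouping)
  if (nlevels(grouping) != 2)
    stop("grouping must have exactly two levels", call. = FALSE)
  if (any(table(grouping) == 0)) stop("empty group", call. = FALSE)
  g1 <- scores$score[grouping == levels(grouping)[1]]
  g2 <- scores$score[grouping == levels(grouping)[2]]
  mannWhitney(g1, g2, alternative = alternative)
}
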