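## Consensus clustering with stability-based model selection, and the
## two-level signature analysis (per-cluster signature genes by one-way
## F-tests with BH correction, k-means gene modules over scaled cluster
## profiles, and hypergeometric over-representation analysis).

#' RNA-seq sample quality control
#'
#' Two rules: a sample is dropped when its total read count is below 25
#' million (equality keeps), or when the sum of ambiguous and no-feature
#' read counts strictly exceeds the sum of gene read-pair counts.
#'
#' @param metrics data.frame with columns `sample`, `totalReads`,
#'   `ambiguous`, `noFeature`, `geneCounts`.
#' @param minReads Minimum total reads (default 25e6).
#' @return data.frame with `sample`, `keep` and `reason`.
#' @export
qcRnaseqSamples <- function(metrics, minReads = 25e6) {
  need <- c("sample", "totalReads", "ambiguous", "noFeature", "geneCounts")
  stopifnot(all(need %in% names(metrics)))
  if (any(unlist(metrics[need[-1]]) < 0))
    stop("negative counts", call. = FALSE)
  lowReads <- metrics$totalReads < minReads
  offTarget <- (metrics$ambiguous + metrics$noFeature) > metrics$geneCounts
  reason <- ifelse(lowReads & offTarget, "low reads; off-target excess",
            ifelse(lowReads, "low reads",
            ifelse(offTarget, "off-target excess", "")))
  data.frame(sample = metrics$sample, keep = !(lowReads | offTarget),
             reason = reason, stringsAsFactors = FALSE)
}

#' Preprocess an expression matrix for clustering
#'
#' Five steps, in order: (1) remove rows where more than `naFraction` of
#' samples are NA (strictly more; exactly 25\% is retained); (2) impute
#' remaining NAs by the row median; (3) winsorize each row at its 5th and
#' 95th percentiles (the default quantile rule of [stats::quantile()],
#' type 7); (4) remove zero-variance rows; (5) remove rows whose variance
#' falls below the 5th percentile of the remaining row variances.
#'
#' @param mat Numeric matrix, genes x samples, possibly with NAs.
#' @param naFraction Maximum tolerated NA fraction per row (default 0.25).
#' @param winsorProbs Winsorization quantiles (default `c(0.05, 0.95)`).
#' @param varQuantile Low-variance removal quantile (default 0.05).
#' @return Filtered numeric matrix.
#' @export
preprocessMatrix <- function(mat, naFraction = 0.25,
                             winsorProbs = c(0.05, 0.95),
                             varQuantile = 0.05) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  naFrac <- rowMeans(is.na(mat))
  mat <- mat[naFrac <= naFraction, , drop = FALSE]
  if (anyNA(mat)) {
    med <- apply(mat, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- med[idx[, 1]]
  }
  if (nrow(mat)) {
    qs <- t(apply(mat, 1, stats::quantile, probs = winsorProbs))
    mat <- pmax(pmin(mat, qs[, 2]), qs[, 1])
  }
  v <- apply(mat, 1, stats::var)
  mat <- mat[v > 0, , drop = FALSE]
  v <- v[v > 0]
  if (length(v)) {
    cut <- stats::quantile(v, varQuantile)
    mat <- mat[v >= cut, , drop = FALSE]
  }
  if (!nrow(mat)) stop("empty matrix after filtering", call. = FALSE)
  mat
}

featureScore <- function(mat, method) {
  switch(method,
         sd = apply(mat, 1, stats::sd),
         mad = apply(mat, 1, stats::mad),
         cv = apply(mat, 1, function(x) stats::sd(x) / abs(mean(x))),
         stop("unknown feature method: ", method, call. = FALSE))
}

basePartition <- function(mat, k, method) {
  ## mat: features x samples; partition the samples
  x <- t(mat)
  switch(method,
         kmeans = stats::kmeans(x, centers = k, nstart = 5)$cluster,
         pam = cluster::pam(x, k = k, cluster.only = TRUE),
         hclust = stats::cutree(stats::hclust(stats::dist(x), "ward.D2"),
                                k = k),
         stop("unknown base method: ", method, call. = FALSE))
}

## pair-level agreement between two partitions over the same samples
pairAgreement <- function(a, b) {
  n <- length(a)
  if (n < 2) return(NA_real_)
  pa <- outer(a, a, "==")[upper.tri(diag(n))]
  pb <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(pa == pb)
}

## Jaccard similarity of the co-clustered pair sets of two partitions
pairJaccard <- function(a, b) {
  n <- length(a)
  pa <- outer(a, a, "==")[upper.tri(diag(n))]
  pb <- outer(b, b, "==")[upper.tri(diag(n))]
  if (!any(pa | pb)) return(NA_real_)
  sum(pa & pb) / sum(pa | pb)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same samples.
#'
#' @param a,b Label vectors of equal length.
#' @return The ARI (1 = identical partitions up to relabelling).
#' @export
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  maxIdx <- (ai + bj) / 2
  if (maxIdx == expected) return(1)
  (nij - expected) / (maxIdx - expected)
}

#' Consensus partitioning with subsampling
#'
#' Selects the top `nFeatures` rows by the feature-selection score, then,
#' for each candidate k, repeatedly clusters random subsamples of the
#' samples and accumulates a consensus matrix: entry (i, j) is the
#' fraction of co-sampled runs in which i and j were co-clustered. Final
#' labels per k come from a hierarchical cut (average linkage) of
#' 1 - consensus. Stability metrics per k are computed by
#' [evaluateStability()]. The chosen k is the one with the highest 1-PAC,
#' exact ties broken by mean silhouette.
#'
#' @param mat Preprocessed matrix, genes x samples.
#' @param featureMethod `"sd"`, `"mad"` or `"cv"`.
#' @param baseMethod `"kmeans"`, `"pam"` or `"hclust"`.
#' @param kRange Candidate numbers of clusters (default 2:6).
#' @param nResamples Subsampled partitions per k (default 50).
#' @param subsampleFraction Fraction of samples per resample (default 0.8).
#' @param nFeatures Number of top-variable features used (default 2000).
#' @param seed Integer seed; resampling is fully reproducible.
#' @return A [ConsensusResult-class].
#' @export
consensusPartition <- function(mat, featureMethod = "sd",
                               baseMethod = "pam", kRange = 2:6,
                               nResamples = 50, subsampleFraction = 0.8,
                               nFeatures = 2000, seed = 1) {
  n <- ncol(mat)
  if (max(kRange) >= n) stop("kRange must lie in 2..n-1", call. = FALSE)
  sc <- featureScore(mat, featureMethod)
  top <- order(sc, decreasing = TRUE)[seq_len(min(nFeatures, nrow(mat)))]
  mat <- mat[top, , drop = FALSE]
  nSub <- max(ceiling(subsampleFraction * n), max(kRange) + 1)
  consensus <- list(); labels <- list()
  metrics <- data.frame()
  resampleParts <- list()
  for (k in kRange) {
    set.seed(childSeed(seed, k))
    hits <- matrix(0, n, n); tries <- matrix(0, n, n)
    parts <- vector("list", nResamples)
    for (b in seq_len(nResamples)) {
      idx <- sort(sample.int(n, nSub))
      cl <- basePartition(mat[, idx, drop = FALSE], k, baseMethod)
      co <- outer(cl, cl, "==")
      hits[idx, idx] <- hits[idx, idx] + co
      tries[idx, idx] <- tries[idx, idx] + 1
      parts[[b]] <- list(idx = idx, labels = cl)
    }
    M <- ifelse(tries > 0, hits / pmax(tries, 1), 0)
    diag(M) <- 1
    M <- (M + t(M)) / 2
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    lab <- stats::cutree(hc, k = k)
    kc <- as.character(k)
    consensus[[kc]] <- M
    labels[[kc]] <- lab
    resampleParts[[kc]] <- parts
    metrics <- rbind(metrics, evaluateStabilityImpl(
      M, lab, parts, prevLabels = labels[[as.character(k - 1)]]))
  }
  metrics$k <- kRange
  metrics <- metrics[, c("k", setdiff(names(metrics), "k"))]
  ## highest 1-PAC wins; exact ties broken by mean silhouette
  ord <- order(-metrics$onePAC, -metrics$meanSilhouette)
  bestK <- kRange[ord[1]]
  new("ConsensusResult", consensus = consensus, metrics = metrics,
      labels = labels,
      chosen = list(featureMethod = featureMethod,
                    baseMethod = baseMethod, k = bestK))
}

evaluateStabilityImpl <- function(M, lab, parts = NULL, prevLabels = NULL,
                                  pacInterval = c(0.1, 0.9)) {
  off <- M[upper.tri(M)]
  pac <- mean(off > pacInterval[1] & off < pacInterval[2])
  sil <- if (length(unique(lab)) > 1) {
    s <- cluster::silhouette(lab, stats::as.dist(1 - M))
    mean(s[, "sil_width"])
  } else NA_real_
  conc <- if (!is.null(parts)) {
    mean(vapply(parts, function(p)
      pairAgreement(p$labels, lab[p$idx]), numeric(1)), na.rm = TRUE)
  } else NA_real_
  jac <- if (!is.null(prevLabels)) pairJaccard(lab, prevLabels) else
    NA_real_
  data.frame(onePAC = 1 - pac, meanSilhouette = sil, concordance = conc,
             jaccardPrevK = jac)
}

#' Stability metrics of a consensus matrix
#'
#' PAC is the fraction of off-diagonal consensus entries strictly inside
#' the ambiguous interval (default (0.1, 0.9)); 1-PAC is reported.
#' Concordance is the mean pair-level agreement between each resample
#' partition and the final labels (when resample partitions are
#' available); the Jaccard index compares the co-clustered pair sets at k
#' and k - 1. Mean silhouette is computed on the 1 - consensus distance.
#'
#' @param result A [ConsensusResult-class].
#' @param k Which k to evaluate.
#' @param pacInterval Ambiguity interval for PAC.
#' @return One-row data.frame of metrics.
#' @export
evaluateStability <- function(result, k, pacInterval = c(0.1, 0.9)) {
  kc <- as.character(k)
  M <- result@consensus[[kc]]
  if (is.null(M)) stop("no consensus matrix computed for k = ", k,
                       call. = FALSE)
  evaluateStabilityImpl(M, result@labels[[kc]],
                        prevLabels = result@labels[[as.character(k - 1)]],
                        pacInterval = pacInterval)
}

#' Grid search over feature and base methods
#'
#' Runs [consensusPartition()] for every combination and selects the
#' configuration with the highest 1-PAC at its chosen k, breaking ties by
#' mean silhouette.
#'
#' @param mat Preprocessed matrix.
#' @param featureMethods,baseMethods Character vectors of methods.
#' @param ... Passed to [consensusPartition()].
#' @return list with `best` (a [ConsensusResult-class]) and `summary`
#'   (one row per combination).
#' @export
consensusGrid <- function(mat, featureMethods = c("sd", "mad", "cv"),
                          baseMethods = c("kmeans", "pam", "hclust"),
                          ...) {
  combos <- expand.grid(featureMethod = featureMethods,
                        baseMethod = baseMethods,
                        stringsAsFactors = FALSE)
  runs <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    res <- consensusPartition(mat, featureMethod = combos$featureMethod[i],
                              baseMethod = combos$baseMethod[i], ...)
    m <- res@metrics[res@metrics$k == res@chosen$k, ]
    runs[[i]] <- res
    rows[[i]] <- data.frame(featureMethod = combos$featureMethod[i],
                            baseMethod = combos$baseMethod[i],
                            k = res@chosen$k, onePAC = m$onePAC,
                            meanSilhouette = m$meanSilhouette)
  }
  summary <- do.call(rbind, rows)
  best <- order(-summary$onePAC, -summary$meanSilhouette)[1]
  list(best = runs[[best]], summary = summary)
}

#' Signature genes by one-way F-tests
#'
#' Per-gene one-way fixed-effects ANOVA across the sample clusters,
#' Benjamini-Hochberg adjusted. Significant genes are assigned to the
#' cluster with the highest mean expression. Constant genes get F = 0 and
#' p = 1.
#'
#' @param mat Expression matrix, genes x samples.
#' @param labels Cluster labels per sample (>= 2 per cluster).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return data.frame: `gene`, `F`, `p`, `q`, `significant`, `cluster`
#'   (NA unless significant) and per-cluster means.
#' @export
signatureGenes <- function(mat, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  g <- nlevels(labels)
  if (any(table(labels) < 2))
    stop("every cluster needs at least 2 samples", call. = FALSE)
  n <- ncol(mat)
  groupMeans <- vapply(levels(labels), function(l)
    rowMeans(mat[, labels == l, drop = FALSE]), numeric(nrow(mat)))
  if (!is.matrix(groupMeans))   # single-gene input
    groupMeans <- matrix(groupMeans, nrow = nrow(mat),
                         dimnames = list(rownames(mat), levels(labels)))
  grand <- rowMeans(mat)
  sizes <- as.numeric(table(labels))
  ssb <- drop((groupMeans - grand)^2 %*% sizes)
  ssw <- rowSums((mat - groupMeans[, as.integer(labels)])^2)
  Fstat <- (ssb / (g - 1)) / (ssw / (n - g))
  Fstat[ssw == 0 & ssb == 0] <- 0
  Fstat[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(Fstat, g - 1, n - g, lower.tail = FALSE)
  p[Fstat == 0] <- 1
  q <- bhFdr(p)
  sig <- q < alpha
  cl <- colnames(groupMeans)[max.col(groupMeans, ties.method = "first")]
  cl[!sig] <- NA
  out <- data.frame(gene = rownames(mat), F = Fstat, p = p, q = q,
                    significant = sig, cluster = cl,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, stats::setNames(as.data.frame(groupMeans),
                             paste0("mean.", colnames(groupMeans))))
}

#' Gene modules by k-means on scaled cluster profiles
#'
#' Signature genes are summarized by their mean expression per sample
#' cluster, each profile row-standardized (mean 0, sd 1), and grouped by
#' k-means with `nInit` restarts under a fixed seed. Modules are labelled
#' M1, M2, ... by the sample cluster at which their mean profile peaks
#' (ties by module size).
#'
#' @param mat Expression matrix restricted to signature genes.
#' @param labels Sample cluster labels.
#' @param k Number of modules (default 3).
#' @param seed Integer seed.
#' @param nInit k-means restarts (default 25).
#' @return A [GeneModuleSet-class].
#' @export
geneModules <- function(mat, labels, k = 3, seed = 1, nInit = 25) {
  labels <- as.factor(labels)
  if (nrow(mat) < k) stop("k exceeds the number of genes", call. = FALSE)
  prof <- vapply(levels(labels), function(l)
    rowMeans(mat[, labels == l, drop = FALSE]), numeric(nrow(mat)))
  scaled <- t(scale(t(prof)))
  scaled[is.nan(scaled)] <- 0
  set.seed(childSeed(seed, 101))
  km <- stats::kmeans(scaled, centers = k, nstart = nInit)
  peak <- apply(km$centers, 1, which.max)
  sizes <- as.numeric(table(factor(km$cluster, levels = seq_len(k))))
  ord <- order(peak, -sizes)
  newId <- match(seq_len(k), ord)
  moduleNames <- paste0("M", newId[km$cluster])
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("M", seq_len(k))
  centers <- t(scale(t(centers)))
  centers[is.nan(centers)] <- 0
  new("GeneModuleSet",
      modules = data.frame(gene = rownames(mat), module = moduleNames,
                           stringsAsFactors = FALSE),
      profiles = centers)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test (including the observed overlap) of each
#' gene set against a module, BH-corrected across sets.
#'
#' @param moduleGenes Character vector (subset of `universe`).
#' @param geneSets Named list of character vectors (subsets of
#'   `universe`).
#' @param universe Character vector of all testable genes.
#' @param qMax Significance level on adjusted p (default 0.05).
#' @return data.frame: `set`, `overlap`, `setSize`, `p`, `q`,
#'   `significant`.
#' @export
oraEnrichment <- function(moduleGenes, geneSets, universe, qMax = 0.05) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  moduleGenes <- intersect(unique(moduleGenes), universe)
  N <- length(universe); nMod <- length(moduleGenes)
  res <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    ov <- length(intersect(set, moduleGenes))
    p <- stats::phyper(ov - 1, length(set), N - length(set), nMod,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, setSize = length(set), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out$significant <- out$q < qMax
  out[order(out$p), , drop = FALSE]
}
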