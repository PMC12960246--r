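## Purity/ploidy QC, segment scoring, cohort copy-number burden, region
## classification on GISTIC-style values, and homozygous-deletion calling
## from bin-level log2 ratios.

#' Default arm model for the synthetic genome
#'
#' A simplified genome of 22 autosomes, 100 Mb each, split into a p arm
#' (0-40 Mb) and a q arm (40-100 Mb). Coordinates are 1-based inclusive.
#' Real analyses should supply their own arm model (e.g. from cytobands).
#'
#' @return data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
defaultArmModel <- function() {
  chrom <- rep(paste0("chr", 1:22), each = 2)
  arm <- rep(c("p", "q"), 22)
  start <- rep(c(1, 40e6 + 1), 22)
  end <- rep(c(40e6, 100e6), 22)
  data.frame(chrom = chrom, arm = arm, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Purity/ploidy quality control
#'
#' A sample fails when its two purity estimates disagree by more than
#' `maxDiscrepancy`, when they show the extreme-disagreement pattern (one
#' estimate below `extremeLow` while the other is at or above
#' `extremeHigh`), or when the goodness of fit is below `minGof`. Samples
#' with a missing estimate are reported as `unassessable`, never silently
#' passed. Boundary behaviour: goodness of fit exactly at `minGof` passes.
#'
#' @param pp data.frame with columns `sample`, `purityA`, `purityB`,
#'   `ploidy`, `goodnessOfFit`.
#' @param maxDiscrepancy Maximum tolerated |purityA - purityB|.
#' @param minGof Minimum goodness of fit (percentage).
#' @param extremeLow,extremeHigh Bounds of the extreme-disagreement pattern.
#' @return data.frame with columns `sample`, `status` (`pass` / `fail` /
#'   `unassessable`) and `reasons`.
#' @export
purityQC <- function(pp, maxDiscrepancy = 0.5, minGof = 95,
                     extremeLow = 0.15, extremeHigh = 0.95) {
  need <- c("sample", "purityA", "purityB", "goodnessOfFit")
  if (!all(need %in% names(pp)))
    stop("missing columns: ", paste(setdiff(need, names(pp)),
                                    collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(pp)), function(i) {
    a <- pp$purityA[i]; b <- pp$purityB[i]; gof <- pp$goodnessOfFit[i]
    if (is.na(a) || is.na(b) || is.na(gof))
      return(list(status = "unassessable", reasons = "missing estimate"))
    reasons <- character(0)
    if (abs(a - b) > maxDiscrepancy)
      reasons <- c(reasons, sprintf("purity discrepancy %.3f > %.3f",
                                    abs(a - b), maxDiscrepancy))
    if (min(a, b) < extremeLow && max(a, b) >= extremeHigh)
      reasons <- c(reasons, "extreme purity disagreement")
    if (gof < minGof)
      reasons <- c(reasons, sprintf("goodness of fit %.1f < %.1f", gof,
                                    minGof))
    list(status = if (length(reasons)) "fail" else "pass",
         reasons = paste(reasons, collapse = "; "))
  })
  data.frame(sample = pp$sample,
             status = vapply(res, `[[`, "", "status"),
             reasons = vapply(res, `[[`, "", "reasons"),
             stringsAsFactors = FALSE)
}

#' Segment mean on the log2 scale
#'
#' `log2(cn / ploidy)`, the ploidy-normalized segment value. A copy number
#' of zero is capped at the documented floor (default -5), as are values
#' that would fall below it.
#'
#' @param cn Total copy number (>= 0), vectorized.
#' @param ploidy Tumour ploidy (> 0).
#' @param floor Cap for `cn = 0`.
#' @return Numeric vector of segment means.
#' @export
segMean <- function(cn, ploidy, floor = -5) {
  if (any(ploidy <= 0)) stop("ploidy must be > 0", call. = FALSE)
  if (any(cn < 0)) stop("copy number must be >= 0", call. = FALSE)
  out <- suppressWarnings(log2(cn / ploidy))
  pmax(out, floor)
}

#' Classify a region copy-number value
#'
#' Thresholds on GISTIC-style region values: gains above 0.9 are high-level
#' amplifications, gains above 0.25 (and up to 0.9) low-level; losses below
#' -1.3 are high-level deletions, losses from -0.25 down to -1.3 low-level;
#' the interval [-0.25, 0.25] is neutral. Every finite value maps to
#' exactly one class (boundary values 0.9 and -1.3 fall in the low classes).
#'
#' @param g Numeric vector of region values.
#' @return factor with levels `high-del`, `low-del`, `neutral`, `low-amp`,
#'   `high-amp`.
#' @export
classifyRegion <- function(g) {
  if (any(!is.finite(g))) stop("region values must be finite", call. = FALSE)
  cls <- ifelse(g > 0.9, "high-amp",
         ifelse(g > 0.25, "low-amp",
         ifelse(g >= -0.25, "neutral",
         ifelse(g >= -1.3, "low-del", "high-del"))))
  factor(cls, levels = c("high-del", "low-del", "neutral", "low-amp",
                         "high-amp"))
}

## clip segments to an arm, returning clipped lengths and seg means
clipToArm <- function(segs, armStart, armEnd) {
  s <- pmax(segs$start, armStart)
  e <- pmin(segs$end, armEnd)
  keep <- e >= s
  data.frame(len = (e - s + 1)[keep], segMean = segs$segMean[keep])
}

#' Broad, focal and global copy-number burden scores
#'
#' Per-sample burden scores computed from ploidy-normalized segment means.
#' The broad score (BCS) sums |arm-level length-weighted mean segment mean|
#' over arms whose absolute mean exceeds `broadThreshold`. The focal score
#' (FCS) sums, over sub-arm segments (covering less than `focalFraction` of
#' their arm), |segMean| weighted by segment length relative to the arm.
#' Each component is then min-max normalized to [0, 50] across the cohort
#' and the global score (GCS) is their sum, in [0, 100]. GCS is therefore a
#' cohort-relative quantity; only orderings are comparable across cohorts.
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`,
#'   `end` (1-based inclusive) and `segMean`.
#' @param armModel data.frame as [defaultArmModel()].
#' @param broadThreshold Minimum |arm mean| for a broad event (default 0.2).
#' @param focalFraction Maximum fraction of the arm a segment may cover and
#'   still count as focal (default 0.9).
#' @return data.frame with columns `sample`, `bcsRaw`, `fcsRaw`, `bcs`,
#'   `fcs`, `gcs`.
#' @export
computeBurden <- function(segments, armModel = defaultArmModel(),
                          broadThreshold = 0.2, focalFraction = 0.9) {
  need <- c("sample", "chrom", "start", "end", "segMean")
  if (!all(need %in% names(segments)))
    stop("missing columns: ", paste(setdiff(need, names(segments)),
                                    collapse = ", "), call. = FALSE)
  samples <- unique(segments$sample)
  if (length(samples) < 2)
    stop("cohort normalization requires at least two samples",
         call. = FALSE)
  raw <- t(vapply(samples, function(s) {
    segs <- segments[segments$sample == s, ]
    bcs <- 0; fcs <- 0
    for (i in seq_len(nrow(armModel))) {
      arm <- armModel[i, ]
      sub <- segs[segs$chrom == arm$chrom, ]
      if (!nrow(sub)) next
      cl <- clipToArm(sub, arm$start, arm$end)
      if (!nrow(cl)) next
      armLen <- arm$end - arm$start + 1
      armMean <- sum(cl$segMean * cl$len) / sum(cl$len)
      if (abs(armMean) > broadThreshold) bcs <- bcs + abs(armMean)
      focal <- cl$len < focalFraction * armLen
      if (any(focal))
        fcs <- fcs + sum(abs(cl$segMean[focal]) * cl$len[focal] / armLen)
    }
    c(bcs = bcs, fcs = fcs)
  }, numeric(2)))
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    50 * (v - rng[1]) / diff(rng)
  }
  bcs <- minmax(raw[, "bcs"]); fcs <- minmax(raw[, "fcs"])
  data.frame(sample = samples, bcsRaw = raw[, "bcs"], fcsRaw = raw[, "fcs"],
             bcs = bcs, fcs = fcs, gcs = bcs + fcs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expected log2 ratio of a homozygous deletion
#'
#' Under the purity/ploidy mixture model, a region with tumour copy number
#' zero in a sample with purity `rho` and ploidy `psi` has expected log2
#' ratio `log2(2 (1 - rho) / (rho psi + 2 (1 - rho)))`: only the normal
#' cells contribute DNA. For a pure tumour (`rho = 1`) the ratio is
#' unbounded below and the documented floor (default -5) is returned. The
#' threshold is strictly decreasing in both purity and ploidy.
#'
#' @param rho Tumour purity in (0, 1], vectorized.
#' @param psi Tumour ploidy (> 0).
#' @param floor Value returned for `rho = 1` (and lower cap).
#' @return Numeric vector of expected log2 ratios.
#' @export
homdelThreshold <- function(rho, psi, floor = -5) {
  if (any(rho <= 0 | rho > 1)) stop("purity must lie in (0, 1]",
                                    call. = FALSE)
  if (any(psi <= 0)) stop("ploidy must be > 0", call. = FALSE)
  val <- suppressWarnings(log2(2 * (1 - rho) / (rho * psi + 2 * (1 - rho))))
  val[rho == 1] <- floor
  pmax(val, floor)
}

#' Call a homozygous deletion from bin-level log2 ratios
#'
#' Two rules, matched to gene size. The large-gene rule calls a deletion
#' when at least two contiguous in-gene bins have log2 ratios at or below
#' the threshold, or when at least one whole exon (if `exons` are supplied)
#' has zero read coverage in every overlapping bin. The small-gene rule
#' calls a deletion when at least one in-gene bin is at or below the
#' threshold, at least two further in-gene bins are within `closeMargin`
#' of it, and the in-gene mean log2 ratio is lower than the flanking-bin
#' mean by at least `flankDelta`. Because focal deletions commonly extend
#' beyond the gene footprint, the `flankGap` bins immediately adjacent to
#' the gene are skipped before the `flankBins` comparison bins are taken
#' on each side.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `log2` and optionally `coverage`, for one sample.
#' @param threshold Expected homozygous-deletion log2 ratio, from
#'   [homdelThreshold()].
#' @param gene list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param rule `"large-gene"` or `"small-gene"`.
#' @param exons Optional data.frame of exon intervals (`chrom`, `start`,
#'   `end`) for the zero-coverage rule.
#' @param closeMargin Margin above the threshold for "close" bins
#'   (default 0.3).
#' @param flankDelta Required drop of the in-gene mean below the flanking
#'   mean (default 0.5).
#' @param flankBins Number of neighbouring bins taken on each side
#'   (default 5).
#' @param flankGap Bins adjacent to the gene skipped before taking the
#'   flanking bins (default 6).
#' @return list with `status` (`"positive"`, `"negative"`,
#'   `"unassessable"`), `evidence` (the in-gene bins) and `rule`.
#' @export
callHomozygousDeletion <- function(bins, threshold, gene,
                                   rule = c("large-gene", "small-gene"),
                                   exons = NULL, closeMargin = 0.3,
                                   flankDelta = 0.5, flankBins = 5,
                                   flankGap = 6) {
  rule <- match.arg(rule)
  assertScalar(threshold, "threshold")
  bins <- bins[order(bins$chrom, bins$start), ]
  onChrom <- bins[bins$chrom == gene$chrom, ]
  inGene <- onChrom[onChrom$end > gene$start & onChrom$start < gene$end, ]
  if (!nrow(inGene))
    return(list(status = "unassessable", evidence = inGene, rule = rule))
  positive <- FALSE
  if (rule == "large-gene") {
    below <- inGene$log2 <= threshold
    runs <- rle(below)
    if (any(runs$lengths[runs$values] >= 2)) positive <- TRUE
    if (!positive && !is.null(exons) && "coverage" %in% names(inGene)) {
      for (i in seq_len(nrow(exons))) {
        ex <- exons[i, ]
        if (ex$chrom != gene$chrom) next
        over <- onChrom[onChrom$end > ex$start & onChrom$start < ex$end, ]
        if (nrow(over) && all(over$coverage == 0)) { positive <- TRUE; break }
      }
    }
  } else {
    below <- inGene$log2 <= threshold
    close <- inGene$log2 <= threshold + closeMargin
    left <- onChrom[onChrom$end <= gene$start, ]
    right <- onChrom[onChrom$start >= gene$end, ]
    dropTail <- function(df, k) if (nrow(df) > k)
      df[seq_len(nrow(df) - k), , drop = FALSE] else df[0, , drop = FALSE]
    leftFlank <- utils::tail(dropTail(left, flankGap), flankBins)
    rightFlank <- utils::head(
      if (nrow(right) > flankGap) right[-seq_len(flankGap), , drop = FALSE]
      else right[0, , drop = FALSE], flankBins)
    flankVals <- c(leftFlank$log2, rightFlank$log2)
    flankOK <- length(flankVals) == 0 ||
      mean(inGene$log2) <= mean(flankVals) - flankDelta
    positive <- any(below) && sum(close) >= 3 && flankOK
  }
  list(status = if (positive) "positive" else "negative",
       evidence = inGene, rule = rule)
}
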