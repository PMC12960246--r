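# Hand-built fixtures shared across test files.

# Three-caller fixture: callers A (5 records), B (3), C (4); sites s1
# (A+B) and s2 (A+C) reach the 2-of-3 consensus, s3 is a BRAF p.V600E
# rescue seen by A only, and the remaining 7 records are singletons that
# must be dropped. Expected consensus: exactly 3 records.
toyCallerFixture <- function() {
  mk <- function(caller, pos, gene = NA, pchange = NA) {
    data.frame(sample = "S1", chrom = "chr7", pos = pos, ref = "A",
               alt = "T", caller = caller, baseq = 35, strandBias = FALSE,
               gene = gene, proteinChange = pchange,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("A", 100), mk("B", 100),                       # s1: consensus
    mk("A", 200), mk("C", 200),                       # s2: consensus
    mk("A", 300, "BRAF", "p.V600E"),                  # s3: rescue
    mk("A", 400), mk("A", 500),                       # A singletons
    mk("B", 600), mk("B", 700),                       # B singletons
    mk("C", 800), mk("C", 900), mk("C", 1000))        # C singletons
}

# 77-sample RNA-seq QC fixture with exactly 33 failures (20 low-read,
# 10 off-target, 3 failing both).
qcMetricsFixture <- function() {
  n <- 77
  m <- data.frame(sample = sprintf("R%02d", 1:n),
                  totalReads = rep(30e6, n), ambiguous = rep(1e6, n),
                  noFeature = rep(1e6, n), geneCounts = rep(20e6, n))
  m$totalReads[1:20] <- 24e6
  m$ambiguous[21:30] <- 15e6
  m$noFeature[21:30] <- 10e6
  m$totalReads[31:33] <- 10e6
  m$ambiguous[31:33] <- 25e6
  m
}

# Planted three-cluster expression matrix built directly: 60 genes, each
# block elevated in one cluster, i.i.d. Gaussian noise elsewhere.
plantedClusterMatrix <- function(nPer = 10, noise = 0.5, seed = 42) {
  set.seed(seed)
  n <- 3 * nPer
  labels <- rep(1:3, each = nPer)
  mat <- matrix(rnorm(60 * n, 0, noise), 60, n,
                dimnames = list(sprintf("G%02d", 1:60),
                                sprintf("S%02d", 1:n)))
  for (k in 1:3)
    mat[((k - 1) * 20 + 1):(k * 20), labels == k] <-
      mat[((k - 1) * 20 + 1):(k * 20), labels == k] + 3
  list(mat = mat, labels = labels)
}
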