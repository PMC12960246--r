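mkCounts <- function(mat, hk = NULL) {
  if (!is.null(hk)) rownames(mat)[seq_along(hk)] <- hk
  mat
}

test_that("housekeeping normalization scales, floors and validates", {
  # 3-sample toy: housekeeping geomeans (10, 20, 40), reference 20
  raw <- rbind(HK1 = c(10, 20, 40), HK2 = c(10, 20, 40),
               G1 = c(100, 100, 100), G2 = c(12, 30, 400))
  nr <- normalizeCounts(raw, c("HK1", "HK2"))
  expect_equal(unname(nr$factors), c(2, 1, 0.5))
  # raw count 12 scaled by 2 = 24 stays; 12 with factor 1 floors to 20
  raw2 <- raw; raw2["G2", ] <- c(12, 12, 12)
  nr2 <- normalizeCounts(raw2, c("HK1", "HK2"))
  expect_equal(unname(nr2$log2["G2", 2]), log2(20))  # floored, then log2
  expect_equal(unname(nr2$log2["G2", 1]), log2(24))  # scaled, then floor
  expect_true(all(nr2$log2 >= log2(20)))

  # identical housekeeping profile: factors all 1
  raw3 <- rbind(HK1 = c(30, 30, 30), G1 = c(5, 50, 500))
  expect_equal(unname(normalizeCounts(raw3, "HK1")$factors), c(1, 1, 1))

  raw4 <- raw; raw4["HK1", 2] <- 0
  expect_error(normalizeCounts(raw4, c("HK1", "HK2")), "HK1")
})

test_that("RNA-seq normalization: size factors, batch centring, floor", {
  set.seed(21)
  base <- matrix(rpois(300, 50), 30, 10,
                 dimnames = list(sprintf("G%02d", 1:30),
                                 sprintf("S%02d", 1:10)))
  # columns that are scalar multiples of one column: factors proportional
  mult <- c(1, 2, 4)
  mat <- cbind(base[, 1], base[, 1] * 2, base[, 1] * 4)
  colnames(mat) <- paste0("X", 1:3)
  sf <- normalizeRnaseq(mat)$sizeFactors
  expect_equal(unname(sf / sf[1]), mult, tolerance = 1e-9)

  # single batch: identity with the no-batch result
  n1 <- normalizeRnaseq(base)
  n2 <- normalizeRnaseq(base, batch = rep("b1", 10))
  expect_equal(n1$log2, n2$log2)

  # two identical batches shifted by one log2 unit: centring removes it
  shifted <- cbind(base, base * 2)
  colnames(shifted) <- sprintf("S%02d", 1:20)
  nb <- normalizeRnaseq(shifted, batch = rep(c("b1", "b2"), each = 10))
  expect_equal(nb$log2[, 1:10], nb$log2[, 11:20],
               ignore_attr = TRUE, tolerance = 1e-9)

  expect_true(all(normalizeRnaseq(matrix(0:3, 2))$log2 >= 1 + 2^-10))
  expect_error(normalizeRnaseq(base, batch = c(rep("a", 9), "b")),
               "single sample")
})

test_that("panel training recovers planted genes and matches the SVD", {
  # zero-noise fixture: 10 acral-only + 10 cutaneous-only expressed genes
  labels <- rep(c("acral", "cutaneous"), each = 10)
  mat <- matrix(5, 40, 20,
                dimnames = list(c(sprintf("A%02d", 1:10),
                                  sprintf("C%02d", 1:10),
                                  sprintf("N%02d", 1:20)),
                                sprintf("S%02d", 1:20)))
  mat[1:10, labels == "acral"] <- 8
  mat[11:20, labels == "cutaneous"] <- 8
  set.seed(22)
  mat <- mat + matrix(rnorm(800, 0, 1e-3), 40, 20)
  panel <- trainPanel(mat, labels)
  expect_setequal(acralGenes(panel), sprintf("A%02d", 1:10))
  expect_setequal(cutaneousGenes(panel), sprintf("C%02d", 1:10))

  # loadings match an independent SVD oracle on a 6x4 toy with planted
  # class structure (two genes up in each class, two neutral)
  set.seed(23)
  toy <- matrix(5 + rnorm(24, 0, 0.2), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  toyLabels <- c("acral", "acral", "cutaneous", "cutaneous")
  toy[1:2, 1:2] <- toy[1:2, 1:2] + 2
  toy[3:4, 3:4] <- toy[3:4, 3:4] + 2
  p2 <- trainPanel(toy, toyLabels, nGenes = 2)
  ctr <- t(toy) - rep(colMeans(t(toy)), each = 4)
  sv <- svd(ctr)
  v <- sv$v[, panelComponent(p2)]
  names(v) <- rownames(toy)
  ld <- panelLoadings(p2)
  v <- v[names(ld)]
  sgn <- sign(sum(v * ld))
  expect_equal(unname(ld), unname(sgn * v), tolerance = 1e-9)

  expect_error(trainPanel(mat, labels, nGenes = 30), "fewer candidate")
  expect_error(trainPanel(matrix(1, 40, 20,
                                 dimnames = dimnames(mat)), labels),
               "degenerate")
})

test_that("the label-associated component is found beyond PC1", {
  # dominant sample-level variation on all genes pushes the class signal
  # to the second component, as in NanoString training data
  set.seed(24)
  n <- 20
  labels <- rep(c("acral", "cutaneous"), each = n / 2)
  common <- rnorm(n, 0, 4)
  mat <- matrix(6, 40, n, dimnames = list(sprintf("G%02d", 1:40),
                                          sprintf("S%02d", 1:n)))
  mat <- sweep(mat, 2, common, `+`)
  mat[1:10, labels == "acral"] <- mat[1:10, labels == "acral"] + 1.5
  mat[11:20, labels == "cutaneous"] <-
    mat[11:20, labels == "cutaneous"] + 1.5
  mat <- mat + matrix(rnorm(40 * n, 0, 0.05), 40, n)
  panel <- trainPanel(mat, labels)
  expect_equal(panelComponent(panel), 2L)
  expect_setequal(acralGenes(panel), sprintf("G%02d", 1:10))
})

test_that("panel products and A:C scores follow the closed forms", {
  x <- c(a = 2, b = 3, c = 4)
  expect_equal(panelProduct(x, c("a", "b")), 6)
  expect_equal(panelProduct(x, character(0)), 1)
  expect_equal(panelProduct(rep(3, 5) |> setNames(letters[1:5]),
                            letters[1:5]), 3^5)
  expect_error(panelProduct(x, "zz"), "missing gene")

  panel <- new("ScorePanel", acralGenes = sprintf("A%d", 1:10),
               cutaneousGenes = sprintf("C%d", 1:10),
               loadings = setNames(c(rep(1, 10), rep(-1, 10)),
                                   c(sprintf("A%d", 1:10),
                                     sprintf("C%d", 1:10))),
               component = 2L, training = list())
  mat <- matrix(4, 20, 3, dimnames = list(c(sprintf("A%d", 1:10),
                                            sprintf("C%d", 1:10)),
                                          c("s1", "s2", "s3")))
  # symmetric input: score exactly 1
  expect_equal(acScore(mat, panel)$score, c(1, 1, 1))
  # acral side at 5, cutaneous at 4: (5/4)^10
  mat2 <- mat; mat2[1:10, 1] <- 5
  expect_equal(acScore(mat2, panel)$score[1], 1.25^10, tolerance = 1e-9)
  # equal panel sizes: multiplying all log2 values cancels out
  expect_equal(acScore(mat2 * 3, panel)$score, acScore(mat2, panel)$score,
               tolerance = 1e-9)
})

test_that("label swap inverts the score and sides", {
  set.seed(25)
  labels <- rep(c("acral", "cutaneous"), each = 8)
  mat <- matrix(rnorm(40 * 16, 6), 40, 16,
                dimnames = list(sprintf("G%02d", 1:40),
                                sprintf("S%02d", 1:16)))
  mat[1:10, labels == "acral"] <- mat[1:10, labels == "acral"] + 2
  mat[11:20, labels == "cutaneous"] <-
    mat[11:20, labels == "cutaneous"] + 2
  mat <- pmax(mat, 1.1)
  p1 <- trainPanel(mat, labels)
  p2 <- trainPanel(mat, ifelse(labels == "acral", "cutaneous", "acral"))
  expect_setequal(acralGenes(p2), cutaneousGenes(p1))
  expect_setequal(cutaneousGenes(p2), acralGenes(p1))
  s1 <- acScore(mat, p1)$score
  s2 <- acScore(mat, p2)$score
  expect_equal(s2, 1 / s1, tolerance = 1e-9)
})

test_that("sample-wide multiplicative factors cancel after normalization", {
  set.seed(26)
  raw <- matrix(rpois(40 * 6, 200), 40, 6,
                dimnames = list(c(sprintf("HK%d", 1:5),
                                  sprintf("G%02d", 1:35)),
                                sprintf("S%d", 1:6)))
  hk <- sprintf("HK%d", 1:5)
  panel <- new("ScorePanel", acralGenes = sprintf("G%02d", 1:10),
               cutaneousGenes = sprintf("G%02d", 11:20),
               loadings = setNames(c(rep(1, 10), rep(-1, 10)),
                                   sprintf("G%02d", 1:20)),
               component = 2L, training = list())
  n1 <- normalizeCounts(raw, hk)
  s1 <- acScore(n1$log2, panel)$score
  raw2 <- raw; raw2[, 3] <- raw2[, 3] * 7     # global factor on sample 3
  s2 <- acScore(normalizeCounts(raw2, hk,
                                reference = n1$reference)$log2,
                panel)$score
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("scores are blind to a panel-disjoint oncogene module", {
  cfg <- defaultSimConfig()$expression
  cfg$dispersion <- 0
  labels <- data.frame(sample = sprintf("S%02d", 1:12), class = "acral",
                       cluster = NA_integer_, braf = FALSE,
                       stringsAsFactors = FALSE)
  sim <- simulateExpression(labels, cfg, seed = 27)
  hk <- sim$genes$housekeeping
  norm1 <- normalizeCounts(sim$counts, hk)
  # plant a "BRAF-downstream" module on background genes only
  shifted <- sim$counts
  bg <- sim$genes$background[1:30]
  shifted[bg, 1:6] <- shifted[bg, 1:6] * 4
  norm2 <- normalizeCounts(shifted, hk)
  panel <- new("ScorePanel", acralGenes = sim$genes$vGenes,
               cutaneousGenes = sim$genes$cGenes,
               loadings = setNames(c(rep(1, 10), rep(-1, 10)),
                                   c(sim$genes$vGenes, sim$genes$cGenes)),
               component = 2L, training = list())
  expect_equal(acScore(norm1$log2, panel)$score,
               acScore(norm2$log2, panel)$score, tolerance = 1e-9)
})

test_that("group comparison delegates to the rank test", {
  sc <- data.frame(sample = sprintf("S%d", 1:8),
                   score = c(1, 1, 1, 1, 1, 1, 1, 1))
  g <- factor(rep(c("a", "b"), 4))
  expect_equal(compareScores(sc, g)$p.value, 1)
  sc$score <- c(1, 10, 2, 11, 3, 12, 4, 13)
  r <- compareScores(sc, g, alternative = "less")
  expect_lt(r$p.value, 0.05)
  expect_error(compareScores(sc, factor(rep("a", 8))), "two levels")
})
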