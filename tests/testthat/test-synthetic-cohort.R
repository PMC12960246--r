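test_that("ancestry simulation is a calibrated Dirichlet", {
  a <- simulateAncestry(200, seed = 41)
  expect_equal(unname(rowSums(a)), rep(1, 200), tolerance = 1e-12)
  expect_true(all(a > 0))

  # symmetric concentrations: component medians agree and approach 1/3
  sym <- simulateAncestry(4000, alphas = c(30, 30, 30), seed = 42)
  med <- unname(apply(sym, 2, median))
  expect_equal(med, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(med, rep(qbeta(0.5, 30, 60), 3), tolerance = 0.02)

  # default calibration reproduces the cohort medians
  d <- simulateAncestry(5000, seed = 43)
  expect_equal(unname(apply(d, 2, median)), c(0.81, 0.136, 0.025),
               tolerance = 0.03)

  expect_error(simulateAncestry(10, alphas = c(1, -1, 1)), "> 0")
  expect_error(simulateAncestry(0), ">= 1")
})

test_that("driver simulation hits marginals and responds to ancestry", {
  n <- 5000
  anc <- simulateAncestry(n, seed = 44)
  set.seed(45)
  cov <- data.frame(female = rbinom(n, 1, 0.587))
  drv <- simulateDrivers(anc, cov, seed = 46)
  freq <- table(factor(ifelse(drv$category == "multi-hit",
                              drv$driver1, drv$category),
                       levels = c("NRAS", "KIT", "BRAF", "NF1"))) / n
  expect_equal(unname(c(freq)), c(0.14, 0.14, 0.13, 0.09),
               tolerance = 0.25)  # +/- ~3 percentage points relative
  expect_true(all(abs(c(freq) - c(0.14, 0.14, 0.13, 0.09)) < 0.03))

  # null European effect: BRAF rate flat in EUR
  coefs <- defaultSimConfig()$drivers
  coefs$eurLogOR["BRAF"] <- 0
  drv0 <- simulateDrivers(anc, cov, coefs, seed = 47)
  braf0 <- drv0$category == "BRAF"
  hi <- anc[, "eur"] > 0.5
  expect_lt(abs(mean(braf0[hi]) - mean(braf0[!hi])), 0.05)

  # positive effect: empirical BRAF rate increases with EUR
  braf <- drv$category %in% "BRAF"
  fit <- logisticFit(cbind(eur = anc[, "eur"]), as.numeric(braf))
  expect_gt(fit$coefficients["eur"], 1)

  expect_error(simulateDrivers(anc, cov[1:10, , drop = FALSE]),
               "mismatch")
})

test_that("expression: deterministic limit separates lineages", {
  cfg <- defaultSimConfig()$expression
  cfg$dispersion <- 0
  labels <- data.frame(sample = sprintf("S%02d", 1:10),
                       class = rep(c("acral", "cutaneous"), 5),
                       cluster = NA_integer_, braf = FALSE,
                       stringsAsFactors = FALSE)
  sim <- simulateExpression(labels, cfg, seed = 48)
  vMean <- colMeans(log2(sim$counts[sim$genes$vGenes, ]))
  cMean <- colMeans(log2(sim$counts[sim$genes$cGenes, ]))
  d <- vMean - cMean
  expect_true(all(d[labels$class == "acral"] > 0))
  expect_true(all(d[labels$class == "cutaneous"] < 0))
  # zero overlap between the two classes (AUROC = 1 territory)
  expect_gt(min(d[labels$class == "acral"]),
            max(d[labels$class == "cutaneous"]))

  # BRAF-flagged acral samples shift toward the cutaneous program
  labels2 <- labels; labels2$class <- "acral"
  labels2$braf <- rep(c(TRUE, FALSE), 5)
  sim2 <- simulateExpression(labels2, cfg, seed = 48)
  d2 <- colMeans(log2(sim2$counts[sim2$genes$vGenes, ])) -
    colMeans(log2(sim2$counts[sim2$genes$cGenes, ]))
  expect_lt(max(d2[labels2$braf]), min(d2[!labels2$braf]))

  expect_error(simulateExpression(labels,
                                  modifyList(cfg, list(dispersion = -1))),
               "dispersion")
})

test_that("copy-number bins follow the purity/ploidy mixture closed form", {
  cfg <- defaultSimConfig()$cna
  cfg$noiseSd <- 0
  cfg$armAlterProb <- 0
  cfg$focalRate <- 0
  cfg$wgdProb <- 0
  cfg$homdelGenes$prob <- 0

  # pure diploid tumour, no events: all bin ratios exactly 0
  cfg1 <- cfg; cfg1$purityRange <- c(1, 1)
  cn1 <- simulateCopyNumber("S1", 0, cfg1, seed = 49)
  expect_equal(cn1$bins$log2, rep(0, nrow(cn1$bins)))
  expect_equal(unique(cn1$segments$segMean), 0)

  # rho = 0.5, psi = 2, c = 0: ratio exactly -1 in the deleted gene
  cfg2 <- cfg; cfg2$purityRange <- c(0.5, 0.5)
  cfg2$homdelGenes$prob <- c(1, 0)
  cn2 <- simulateCopyNumber("S1", 0, cfg2, seed = 50)
  g <- cfg2$homdelGenes[1, ]
  inGene <- cn2$bins$region == g$gene & cn2$bins$start >= g$start &
    cn2$bins$end <= g$end
  expect_equal(cn2$bins$log2[inGene], rep(-1, sum(inGene)))

  expect_error(simulateCopyNumber("S1", 0,
                                  modifyList(cfg, list(purityRange = c(1.2, 1.2)))),
               "purity")
})

test_that("outcome simulation is null when all effects vanish", {
  cfg <- defaultSimConfig()$outcomes
  cfg$recurrence$driverLogOR <- 0
  cfg$recurrence$stageLogOR <- 0
  cfg$recurrence$agePerYear <- 0
  cfg$survival$driverLogHR <- 0
  cfg$survival$agePerYear <- 0
  set.seed(51)
  n <- 4000
  cov <- data.frame(mutated = rbinom(n, 1, 0.5),
                    advancedStage = rbinom(n, 1, 0.6),
                    age = round(rnorm(n, 61, 12)))
  out <- simulateOutcomes(cov, cfg, seed = 52)
  expect_lt(abs(mean(out$recurrence[cov$mutated == 1]) -
                  mean(out$recurrence[cov$mutated == 0])), 0.05)
  expect_lt(abs(mean(out$death[cov$mutated == 1]) -
                  mean(out$death[cov$mutated == 0])), 0.05)
  expect_true(all(out$timeDeath >= 0 & out$timeRecurrence >= 0))
  expect_true(all(out$recruitmentLag < out$timeDeath))
  expect_error(simulateOutcomes(data.frame(age = 1:5), cfg), "mutated")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- defaultSimConfig(nPatients = 15)
  c1 <- simulateCohort(cfg, seed = 53)
  c2 <- simulateCohort(cfg, seed = 53)
  expect_identical(SummarizedExperiment::assay(cohortExpression(c1)),
                   SummarizedExperiment::assay(cohortExpression(c2)))
  expect_identical(cohortVariants(c1), cohortVariants(c2))
  expect_identical(cohortSegments(c1), cohortSegments(c2))
  expect_identical(cohortClinical(c1), cohortClinical(c2))
  c3 <- simulateCohort(cfg, seed = 54)
  expect_false(identical(cohortVariants(c1), cohortVariants(c3)))
})

test_that("cohort write/read round-trips and manifests track content", {
  co <- simulateCohort(defaultSimConfig(nPatients = 8), seed = 55)
  d <- withr::local_tempdir()
  manifest <- writeCohort(co, d)
  expect_true(all(c("expression.tsv", "clinical.tsv", "truth.json") %in%
                    manifest$file))
  co2 <- readCohort(d)
  expect_equal(SummarizedExperiment::assay(cohortExpression(co)),
               SummarizedExperiment::assay(cohortExpression(co2)))
  expect_equal(cohortSegments(co), cohortSegments(co2),
               tolerance = 1e-12)
  expect_equal(cohortClinical(co)$category, cohortClinical(co2)$category)
  key <- function(v) sort(paste(v$sample, v$chrom, v$pos, v$ref, v$alt,
                                v$caller))
  expect_identical(key(cohortVariants(co)), key(cohortVariants(co2)))

  # checksums change iff file content changes
  m2 <- fileManifest(file.path(d, manifest$file), root = d)
  expect_identical(m2$md5, manifest$md5)
  clinPath <- file.path(d, "clinical.tsv")
  writeLines(c(readLines(clinPath), ""), clinPath)
  m3 <- fileManifest(file.path(d, manifest$file), root = d)
  changed <- m3$md5 != manifest$md5
  expect_identical(m3$file[changed], "clinical.tsv")
})

test_that("written VCFs conform to the format", {
  skip_if_not_installed("VariantAnnotation")
  co <- simulateCohort(defaultSimConfig(nPatients = 6), seed = 56)
  d <- withr::local_tempdir()
  writeCohort(co, d)
  vcfs <- list.files(file.path(d, "vcf"), full.names = TRUE)
  expect_gt(length(vcfs), 0)
  vcf <- VariantAnnotation::readVcf(vcfs[1])
  expect_gt(nrow(vcf), 0)
  back <- readCallerVcf(vcfs[1], caller = "x", sample = "s")
  expect_true(all(c("chrom", "pos", "ref", "alt", "baseq") %in%
                    names(back)))
  expect_true(all(back$baseq >= 30))
})
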