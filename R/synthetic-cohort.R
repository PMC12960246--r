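## Synthetic-cohort generator. Emulates the statistical structure the
## downstream analyses assume: Dirichlet admixture ancestry, mutually
## exclusive MAPK driver mutations whose odds depend on ancestry and sex,
## negative-binomial expression with two melanocyte lineage programs
## (v-type / c-type) and three transcriptional cluster modules, purity- and
## ploidy-contaminated copy-number profiles with planted homozygous
## deletions, and logistic recurrence / proportional-hazards survival
## outcomes. Every planted parameter is recorded in the truth block.

#' Default simulation configuration
#'
#' All defaults are chosen to emulate a realistic admixed acral-melanoma
#' cohort: ancestry concentrations are calibrated by moment matching so the
#' component medians are approximately 81\% Amerindian, 13.6\% European and
#' 2.5\% African; driver intercepts are calibrated so marginal mutation
#' frequencies are approximately NRAS 14\%, KIT 14\%, BRAF 13\% and NF1
#' 9\% under the planted sex effect (odds ratio 3.83 for female patients)
#' and the planted European-ancestry effect on BRAF (2.5 on the log-odds
#' scale); mean mutational burden is 0.95 per megabase over a 50 Mb
#' capture; the recurrence model plants an odds ratio of 5.31 for mutated
#' tumours and the survival model a hazard ratio of 3.19; the copy-number
#' model shares a per-sample latent intensity between mutation rate and
#' arm-level alteration rate so that burden and TMB are correlated.
#'
#' @param nPatients Number of patients (default 92).
#' @return A nested list of configuration blocks.
#' @export
defaultSimConfig <- function(nPatients = 92) {
  list(
    nPatients = nPatients,
    seedOffsets = c(ancestry = 1, clinical = 2, drivers = 3,
                    expression = 4, cna = 5, outcomes = 6, variants = 7),
    ancestryDirichlet = c(amr = 7.880, eur = 1.585, afr = 0.507),
    drivers = list(
      genes = c("NRAS", "KIT", "BRAF", "NF1"),
      intercepts = c(NRAS = -2.0703, KIT = -2.0703, BRAF = -2.5698,
                     NF1 = -2.5121),
      sexLogOR = log(3.83),          # female vs male, all driver genes
      eurLogOR = c(NRAS = 0, KIT = 0, BRAF = 2.5, NF1 = 0),
      multiHitRate = 1 / 92),
    expression = list(
      nBackground = 200,
      nModuleGenes = 40,
      baselineLog2 = 5,
      lineageEffect = 3,             # log2 shift of the lineage program
      clusterEffect = 2,             # log2 shift of a cluster's module
      brafShift = 2,                 # shift of BRAF acral samples to c-type
      dispersion = 0.15,             # NB dispersion; 0 = exact means
      librarySizeRange = c(0.5, 2),  # log-uniform relative library factors
      clusterProbs = c(14, 16, 14) / 44),
    variants = list(
      callers = c("caveman", "mutect2", "varscan2"),
      callerSensitivity = 1,         # 1 = noise-free consensus
      meanTmb = 0.95,                # mutations per megabase
      captureMb = 50,
      tmbLatentSd = 0.6,             # couples TMB to the CNA latent
      baseqRange = c(30, 45)),
    cna = list(
      purityRange = c(0.4, 0.95),
      wgdProb = 0.23,
      armAlterProb = 0.12,
      armLatentCoef = 1.4,           # log-odds per latent unit
      focalRate = 2,
      gainBias = 0.6,                # P(gain | arm event)
      noiseSd = 0.15,
      binSize = 2e4,
      flankSize = 1e6,
      homdelGenes = data.frame(
        gene = c("CDKN2A", "NF1"),
        chrom = c("chr9", "chr17"),
        start = c(21.0e6, 60.0e6),   # 0-based half-open, for bins
        end = c(21.4e6, 60.4e6),
        rule = c("small-gene", "large-gene"),
        prob = c(0.25, 0.05),
        stringsAsFactors = FALSE)),
    outcomes = list(
      recurrence = list(intercept = stats::qlogis(0.372),
                        driverLogOR = log(5.31), stageLogOR = 0.5,
                        agePerYear = 0.02),
      survival = list(baselineHazard = 0.035, driverLogHR = log(3.19),
                      agePerYear = 0.02, horizonYears = 10,
                      recruitmentLagMeanYears = 2.01),
      extraSampleRate = 0.2))        # metastases in addition to primaries
}

#' Simulate admixture ancestry fractions
#'
#' Dirichlet draws (via normalized gamma variates) with concentrations
#' calibrated so the component medians approximate 81\% Amerindian, 13.6\%
#' European and 2.5\% African in large cohorts.
#'
#' @param n Number of patients.
#' @param alphas Three positive concentration parameters (AMR, EUR, AFR).
#' @param seed Integer seed.
#' @return Matrix n x 3 with columns `amr`, `eur`, `afr`, rows summing
#'   to 1.
#' @export
simulateAncestry <- function(n, alphas = defaultSimConfig()$ancestryDirichlet,
                             seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(alphas <= 0)) stop("concentration parameters must be > 0",
                             call. = FALSE)
  if (length(alphas) != 3) stop("three concentrations required",
                                call. = FALSE)
  set.seed(seed)
  g <- matrix(stats::rgamma(n * 3, shape = rep(alphas, each = n)), n, 3)
  out <- g / rowSums(g)
  colnames(out) <- c("amr", "eur", "afr")
  out
}

#' Simulate driver genotypes
#'
#' Multinomial-logit assignment with QWT (no driver) as the reference
#' category: each gene's linear predictor combines its calibrated
#' intercept, the sex effect and its European-ancestry effect. By default
#' each patient carries exactly zero or one driver; with probability
#' `multiHitRate` a second distinct driver is added (multi-hit).
#'
#' @param ancestry Matrix from [simulateAncestry()].
#' @param covariates data.frame with a `female` (0/1) column, one row per
#'   patient.
#' @param coefs Driver coefficient block (see [defaultSimConfig()]).
#' @param seed Integer seed.
#' @return data.frame with `driver1`, `driver2` (NA unless multi-hit) and
#'   `category`.
#' @export
simulateDrivers <- function(ancestry, covariates,
                            coefs = defaultSimConfig()$drivers, seed = 1) {
  n <- nrow(ancestry)
  if (nrow(covariates) != n)
    stop("covariate/ancestry length mismatch", call. = FALSE)
  stopifnot(all(is.finite(unlist(coefs[c("intercepts", "sexLogOR",
                                         "eurLogOR")]))))
  set.seed(seed)
  genes <- coefs$genes
  eta <- sapply(genes, function(g)
    coefs$intercepts[g] + coefs$sexLogOR * covariates$female +
      coefs$eurLogOR[g] * ancestry[, "eur"])
  w <- cbind(exp(eta), QWT = 1)
  pick <- apply(w, 1, function(row) sample(colnames(w), 1, prob = row))
  multi <- stats::rbinom(n, 1, coefs$multiHitRate) == 1 & pick != "QWT"
  driver2 <- rep(NA_character_, n)
  driver2[multi] <- vapply(pick[multi], function(g)
    sample(setdiff(genes, g), 1), character(1))
  category <- ifelse(pick == "QWT", "QWT",
                     ifelse(multi, "multi-hit", pick))
  data.frame(driver1 = ifelse(pick == "QWT", NA, pick), driver2 = driver2,
             category = category, stringsAsFactors = FALSE)
}

## gene universe implied by an expression config
expressionGenes <- function(ex) {
  list(housekeeping = sprintf("HK%02d", 1:10),
       vGenes = sprintf("VTG%02d", 1:10),
       cGenes = sprintf("CTG%02d", 1:10),
       modules = list(M1 = sprintf("EPI%03d", seq_len(ex$nModuleGenes)),
                      M2 = sprintf("PRO%03d", seq_len(ex$nModuleGenes)),
                      M3 = sprintf("OXP%03d", seq_len(ex$nModuleGenes))),
       background = sprintf("BG%03d", seq_len(ex$nBackground)))
}

#' Simulate expression counts
#'
#' Negative-binomial counts with log2 mean = baseline + lineage effect +
#' cluster-module effect + library-size offset. Acral samples express the
#' v-type program, cutaneous samples the c-type program; BRAF-flagged
#' acral samples are shifted toward the c-type program by `brafShift`.
#' With `dispersion = 0` no sampling occurs and the exact means are
#' returned (the deterministic limit used by separation tests).
#'
#' @param labels data.frame with columns `sample`, `class` (`acral` /
#'   `cutaneous`), `cluster` (1-3 or NA) and `braf` (logical).
#' @param config Expression config block (see [defaultSimConfig()]).
#' @param seed Integer seed.
#' @return list: `counts` (genes x samples), `genes` (the gene universe).
#' @export
simulateExpression <- function(labels,
                               config = defaultSimConfig()$expression,
                               seed = 1) {
  gu <- expressionGenes(config)
  all <- unlist(gu, use.names = FALSE)
  if (anyDuplicated(all)) stop("overlapping gene sets", call. = FALSE)
  if (config$nModuleGenes < 1) stop("empty modules", call. = FALSE)
  if (config$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  n <- nrow(labels)
  set.seed(seed)
  lr <- log(config$librarySizeRange)
  libFactor <- exp(stats::runif(n, lr[1], lr[2]) - mean(lr))
  logmu <- matrix(config$baselineLog2, length(all), n,
                  dimnames = list(all, labels$sample))
  for (i in seq_len(n)) {
    if (labels$class[i] == "acral") {
      logmu[gu$vGenes, i] <- logmu[gu$vGenes, i] + config$lineageEffect
      if (isTRUE(labels$braf[i])) {
        logmu[gu$vGenes, i] <- logmu[gu$vGenes, i] - config$brafShift
        logmu[gu$cGenes, i] <- logmu[gu$cGenes, i] + config$brafShift
      }
    } else {
      logmu[gu$cGenes, i] <- logmu[gu$cGenes, i] + config$lineageEffect
    }
    cl <- labels$cluster[i]
    if (!is.na(cl))
      logmu[gu$modules[[cl]], i] <-
        logmu[gu$modules[[cl]], i] + config$clusterEffect
  }
  mu <- sweep(2^logmu, 2, libFactor, `*`)
  counts <- if (config$dispersion == 0) mu else
    matrix(stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$dispersion),
           nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(counts = counts, genes = gu, libFactor = libFactor)
}

#' Simulate copy-number profiles
#'
#' Per sample: purity and ploidy (with a configurable whole-genome
#' duplication rate), arm-level gains/losses whose rate is coupled to the
#' shared latent mutation-intensity, focal events, and planted homozygous
#' deletions at the configured genes. Bin-level log2 ratios follow the
#' purity/ploidy mixture model
#' `log2((rho c + 2 (1 - rho)) / (rho psi + 2 (1 - rho)))` plus Gaussian
#' noise.
#'
#' @param samples Character vector of sample ids.
#' @param latent Numeric latent intensity per sample (default 0).
#' @param config CNA config block (see [defaultSimConfig()]).
#' @param seed Integer seed.
#' @return list: `segments`, `bins`, `purityPloidy`, `homdelTruth`.
#' @export
simulateCopyNumber <- function(samples, latent = rep(0, length(samples)),
                               config = defaultSimConfig()$cna, seed = 1) {
  set.seed(seed)
  arms <- defaultArmModel()
  nS <- length(samples)
  rho <- stats::runif(nS, config$purityRange[1], config$purityRange[2])
  if (any(rho <= 0 | rho > 1)) stop("purity out of (0, 1]", call. = FALSE)
  wgd <- stats::rbinom(nS, 1, config$wgdProb) == 1
  psi <- ifelse(wgd, 4, 2)
  if (any(psi <= 0)) stop("ploidy must be > 0", call. = FALSE)
  rhoB <- pmin(pmax(rho + stats::rnorm(nS, 0, 0.02), 0.05), 1)
  gof <- stats::runif(nS, 95.5, 100)
  hd <- config$homdelGenes
  segs <- list(); bins <- list(); hdTruth <- list()
  for (s in seq_len(nS)) {
    pArm <- stats::plogis(stats::qlogis(config$armAlterProb) +
                            config$armLatentCoef * latent[s])
    homdelFlags <- stats::rbinom(nrow(hd), 1, hd$prob) == 1
    sampleSegs <- list()
    for (a in seq_len(nrow(arms))) {
      arm <- arms[a, ]
      cnArm <- psi[s]
      if (stats::runif(1) < pArm)
        cnArm <- max(0, psi[s] +
                       ifelse(stats::runif(1) < config$gainBias, 1, -1))
      pieces <- data.frame(start = arm$start, end = arm$end, cn = cnArm)
      carve <- function(pieces, fs, fe, cn) {
        out <- list()
        for (p in seq_len(nrow(pieces))) {
          pc <- pieces[p, ]
          if (fe < pc$start || fs > pc$end) { out[[p]] <- pc; next }
          keep <- list()
          if (pc$start < fs)
            keep <- c(keep, list(data.frame(start = pc$start, end = fs - 1,
                                            cn = pc$cn)))
          keep <- c(keep, list(data.frame(start = max(fs, pc$start),
                                          end = min(fe, pc$end), cn = cn)))
          if (pc$end > fe)
            keep <- c(keep, list(data.frame(start = fe + 1, end = pc$end,
                                            cn = pc$cn)))
          out[[p]] <- do.call(rbind, keep)
        }
        do.call(rbind, out)
      }
      nFocal <- stats::rpois(1, config$focalRate / nrow(arms))
      for (f in seq_len(nFocal)) {
        len <- stats::runif(1, 1e6, 8e6)
        fs <- round(stats::runif(1, arm$start, max(arm$start,
                                                   arm$end - len)))
        fe <- min(arm$end, round(fs + len))
        cnF <- max(0, cnArm + sample(c(-1, 1, 2), 1,
                                     prob = c(0.4, 0.4, 0.2)))
        pieces <- carve(pieces, fs, fe, cnF)
      }
      for (h in seq_len(nrow(hd))) {
        if (hd$chrom[h] == arm$chrom && homdelFlags[h] &&
            hd$start[h] >= arm$start - 1 && hd$end[h] <= arm$end) {
          pad <- 1e5
          pieces <- carve(pieces, hd$start[h] + 1 - pad, hd$end[h] + pad, 0)
        }
      }
      pieces <- pieces[order(pieces$start), ]
      pieces$chrom <- arm$chrom
      sampleSegs[[a]] <- pieces
    }
    ss <- do.call(rbind, sampleSegs)
    ss$sample <- samples[s]
    ss$segMean <- segMean(ss$cn, psi[s])
    segs[[s]] <- ss[, c("sample", "chrom", "start", "end", "cn", "segMean")]
    ## bin-level ratios over the homdel gene regions (gene +/- flank)
    for (h in seq_len(nrow(hd))) {
      rs <- hd$start[h] - config$flankSize
      re <- hd$end[h] + config$flankSize
      bStart <- seq(rs, re - config$binSize, by = config$binSize)
      bEnd <- bStart + config$binSize
      mid <- (bStart + bEnd) / 2
      cnBin <- vapply(mid, function(m) {
        seg <- ss[ss$chrom == hd$chrom[h] & ss$start <= m & ss$end >= m, ]
        if (nrow(seg)) seg$cn[1] else psi[s]
      }, numeric(1))
      ratio <- log2((rho[s] * cnBin + 2 * (1 - rho[s])) /
                      (rho[s] * psi[s] + 2 * (1 - rho[s])))
      ratio <- pmax(ratio, -8) + stats::rnorm(length(ratio), 0,
                                              config$noiseSd)
      cov <- pmax(0, round(100 * 2^ratio + stats::rnorm(length(ratio), 0,
                                                        2)))
      bins[[length(bins) + 1]] <- data.frame(
        sample = samples[s], chrom = hd$chrom[h], start = bStart,
        end = bEnd, log2 = ratio, coverage = cov, region = hd$gene[h],
        stringsAsFactors = FALSE)
    }
    hdTruth[[s]] <- data.frame(sample = samples[s], gene = hd$gene,
                               homdel = homdelFlags,
                               stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  allBins <- do.call(rbind, bins)
  rownames(allBins) <- NULL
  list(segments = segments, bins = allBins,
       purityPloidy = data.frame(sample = samples, purityA = rho,
                                 purityB = rhoB, ploidy = psi,
                                 goodnessOfFit = gof, wgd = wgd,
                                 stringsAsFactors = FALSE),
       homdelTruth = {h <- do.call(rbind, hdTruth); rownames(h) <- NULL; h})
}

#' Simulate recurrence and survival outcomes
#'
#' Recurrence follows the planted logistic model (driver log-odds plus
#' stage and age effects); death times follow an exponential
#' proportional-hazards model with the planted hazard ratio,
#' administratively censored at the horizon. A recruitment lag (mean 2.01
#' years, truncated below follow-up) is recorded for delayed-entry
#' analyses.
#'
#' @param covariates data.frame with columns `mutated` (0/1),
#'   `advancedStage` (0/1) and `age`.
#' @param config Outcomes config block.
#' @param seed Integer seed.
#' @return data.frame with recurrence and survival columns.
#' @export
simulateOutcomes <- function(covariates,
                             config = defaultSimConfig()$outcomes,
                             seed = 1) {
  if (!"mutated" %in% names(covariates))
    stop("missing driver column 'mutated'", call. = FALSE)
  set.seed(seed)
  n <- nrow(covariates)
  rc <- config$recurrence
  eta <- rc$intercept + rc$driverLogOR * covariates$mutated +
    rc$stageLogOR * (covariates$advancedStage - mean(covariates$advancedStage)) +
    rc$agePerYear * (covariates$age - mean(covariates$age))
  recurrence <- stats::rbinom(n, 1, stats::plogis(eta))
  sv <- config$survival
  rate <- sv$baselineHazard * exp(sv$driverLogHR * covariates$mutated +
    sv$agePerYear * (covariates$age - mean(covariates$age)))
  tDeath <- stats::rexp(n, rate)
  death <- as.integer(tDeath <= sv$horizonYears)
  timeDeath <- pmin(tDeath, sv$horizonYears)
  timeRecurrence <- ifelse(recurrence == 1,
                           stats::runif(n, 0.1, 0.9) * timeDeath,
                           timeDeath)
  lag <- stats::rexp(n, 1 / sv$recruitmentLagMeanYears)
  recruitmentLag <- pmin(lag, 0.9 * timeDeath)
  data.frame(recurrence = recurrence, timeRecurrence = timeRecurrence,
             death = death, timeDeath = timeDeath,
             recruitmentLag = recruitmentLag)
}

## passenger + driver variant generation, per caller
simulateVariantCalls <- function(clinical, sampleMap, latent, config,
                                 seed) {
  set.seed(seed)
  callers <- config$callers
  recs <- list()
  drvAnno <- list(
    BRAF = list(chrom = "chr7", pos = 140753336, ref = "A", alt = "T",
                pchange = "p.V600E"),
    NRAS = list(chrom = "chr1", pos = 114716126, ref = "C", alt = "T",
                pchange = "p.Q61K"),
    KIT = list(chrom = "chr4", pos = 54727444, ref = "T", alt = "A",
               pchange = "p.L576P"),
    NF1 = list(chrom = "chr17", pos = 31226000, ref = "G", alt = "A",
               pchange = "p.R1000X"))
  for (i in seq_len(nrow(sampleMap))) {
    pid <- sampleMap$patient[i]
    sid <- sampleMap$sample[i]
    pidx <- match(pid, clinical$patient)
    rateTmb <- config$meanTmb *
      exp(config$tmbLatentSd * latent[pidx] - config$tmbLatentSd^2 / 2)
    nPass <- stats::rpois(1, rateTmb * config$captureMb)
    pass <- if (nPass) data.frame(
      sample = sid,
      chrom = paste0("chr", sample(1:22, nPass, replace = TRUE)),
      pos = sample.int(9e7, nPass), ref = sample(c("A", "C", "G", "T"),
                                                 nPass, replace = TRUE),
      alt = NA_character_, gene = NA_character_,
      proteinChange = NA_character_, stringsAsFactors = FALSE) else NULL
    if (!is.null(pass)) {
      alt <- vapply(pass$ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
      pass$alt <- alt
      dup <- duplicated(paste(pass$chrom, pass$pos))
      pass <- pass[!dup, , drop = FALSE]
    }
    drv <- NULL
    genes <- stats::na.omit(c(clinical$driver1[pidx],
                              clinical$driver2[pidx]))
    if (length(genes)) {
      drv <- do.call(rbind, lapply(genes, function(g) {
        an <- drvAnno[[g]]
        data.frame(sample = sid, chrom = an$chrom, pos = an$pos,
                   ref = an$ref, alt = an$alt, gene = g,
                   proteinChange = an$pchange, stringsAsFactors = FALSE)
      }))
    }
    trueVars <- rbind(pass, drv)
    if (is.null(trueVars) || !nrow(trueVars)) next
    trueVars$baseq <- round(stats::runif(nrow(trueVars),
                                         config$baseqRange[1],
                                         config$baseqRange[2]))
    trueVars$strandBias <- FALSE
    for (cl in callers) {
      called <- stats::runif(nrow(trueVars)) <= config$callerSensitivity
      if (!any(called)) next
      sub <- trueVars[called, , drop = FALSE]
      sub$caller <- cl
      recs[[length(recs) + 1]] <- sub
    }
  }
  if (!length(recs)) return(data.frame())
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort
#'
#' Orchestrates all component simulators under one master seed (each
#' component receives a child seed through [childSeed()]), producing a
#' [SyntheticCohort-class] whose truth block records every planted
#' parameter and label.
#'
#' @param config From [defaultSimConfig()].
#' @param seed Master integer seed.
#' @return A [SyntheticCohort-class].
#' @export
simulateCohort <- function(config = defaultSimConfig(), seed = 1) {
  off <- config$seedOffsets
  n <- config$nPatients
  patient <- sprintf("P%03d", seq_len(n))
  anc <- simulateAncestry(n, config$ancestryDirichlet,
                          seed = childSeed(seed, off["ancestry"]))
  set.seed(childSeed(seed, off["clinical"]))
  female <- stats::rbinom(n, 1, 54 / 92)
  age <- round(pmin(pmax(stats::rnorm(n, 61.2, 12), 32), 98))
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(10, 25, 47, 9))
  ulceration <- stats::rbinom(n, 1, 61 / 90)
  site <- sample(c("foot", "hand", "subungual"), n, replace = TRUE,
                 prob = c(76, 4, 12))
  latent <- stats::rnorm(n)
  clinical <- data.frame(patient = patient, female = female, age = age,
                         stage = stage,
                         advancedStage = as.integer(stage %in% c("III",
                                                                 "IV")),
                         ulceration = ulceration, site = site,
                         amr = anc[, "amr"], eur = anc[, "eur"],
                         afr = anc[, "afr"], stringsAsFactors = FALSE)
  drv <- simulateDrivers(anc, clinical, config$drivers,
                         seed = childSeed(seed, off["drivers"]))
  clinical <- cbind(clinical, drv)
  clinical$mutated <- as.integer(clinical$category != "QWT")
  out <- simulateOutcomes(clinical, config$outcomes,
                          seed = childSeed(seed, off["outcomes"]))
  clinical <- cbind(clinical, out)
  ## one primary per patient, plus occasional metastases
  set.seed(childSeed(seed, off["clinical"] + 100))
  primary <- data.frame(patient = patient,
                        sample = paste0(patient, "-T1"), type = "primary",
                        stringsAsFactors = FALSE)
  extra <- patient[stats::runif(n) < config$outcomes$extraSampleRate]
  sampleMap <- rbind(primary, if (length(extra)) data.frame(
    patient = extra, sample = paste0(extra, "-M1"), type = "metastasis",
    stringsAsFactors = FALSE))
  cluster <- sample(seq_len(3), n, replace = TRUE,
                    prob = config$expression$clusterProbs)
  labels <- data.frame(sample = primary$sample, class = "acral",
                       cluster = cluster,
                       braf = clinical$category %in% "BRAF" |
                         (!is.na(clinical$driver2) &
                            clinical$driver2 == "BRAF") |
                         (!is.na(clinical$driver1) &
                            clinical$driver1 == "BRAF"),
                       stringsAsFactors = FALSE)
  expr <- simulateExpression(labels, config$expression,
                             seed = childSeed(seed, off["expression"]))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = expr$counts),
    colData = S4Vectors::DataFrame(labels, row.names = labels$sample))
  cna <- simulateCopyNumber(primary$sample, latent, config$cna,
                            seed = childSeed(seed, off["cna"]))
  calls <- simulateVariantCalls(clinical, sampleMap, latent,
                                config$variants,
                                seed = childSeed(seed, off["variants"]))
  truth <- list(config = config, seed = seed, driverCategory =
                  stats::setNames(clinical$category, patient),
                cluster = stats::setNames(cluster, primary$sample),
                brafFlag = stats::setNames(labels$braf, primary$sample),
                latent = stats::setNames(latent, patient),
                homdel = cna$homdelTruth,
                genes = expr$genes)
  methods::new("SyntheticCohort", expression = se, variants = calls,
               segments = cna$segments, bins = cna$bins,
               purityPloidy = cna$purityPloidy, clinical = clinical,
               truth = truth)
}

#' Write a cohort to plain-text files
#'
#' Writes the expression matrix (TSV, genes as rows), clinical, segment,
#' bin and purity/ploidy tables (TSV), the truth block (JSON), and one VCF
#' v4.2 file per caller per sample, then a manifest with md5 checksums.
#'
#' @param cohort A [SyntheticCohort-class].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  counts <- as.data.frame(SummarizedExperiment::assay(cohort@expression,
                                                      "counts"))
  counts <- cbind(gene = rownames(counts), counts)
  files <- c(wt(counts, "expression.tsv"),
             wt(cohort@clinical, "clinical.tsv"),
             wt(cohort@segments, "segments.tsv"),
             wt(cohort@bins, "bins.tsv"),
             wt(cohort@purityPloidy, "purity_ploidy.tsv"),
             wt(as.data.frame(SummarizedExperiment::colData(
               cohort@expression)), "sample_labels.tsv"))
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort@truth, truthPath, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  files <- c(files, truthPath)
  vcfDir <- file.path(dir, "vcf")
  dir.create(vcfDir, showWarnings = FALSE)
  v <- cohort@variants
  if (nrow(v)) {
    for (sid in unique(v$sample)) for (cl in unique(v$caller)) {
      sub <- v[v$sample == sid & v$caller == cl, , drop = FALSE]
      if (!nrow(sub)) next
      path <- file.path(vcfDir, paste0(sid, "_", cl, ".vcf"))
      writeSimpleVcf(sub, path)
      files <- c(files, path)
    }
  }
  manifest <- fileManifest(files, root = dir)
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

## minimal VCF v4.2 writer for one sample's calls from one caller
writeSimpleVcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chr", 1:22, ",length=248956422>"),
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
    "##INFO=<ID=SB,Number=0,Type=Flag,Description=\"Strand bias\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=PCHANGE,Number=1,Type=String,",
           "Description=\"Protein change\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  info <- vapply(seq_len(nrow(calls)), function(i) {
    parts <- c(sprintf("BQ=%g", calls$baseq[i]),
               if (isTRUE(calls$strandBias[i])) "SB",
               if (!is.na(calls$gene[i]))
                 sprintf("GENE=%s", calls$gene[i]),
               if (!is.na(calls$proteinChange[i]))
                 sprintf("PCHANGE=%s", calls$proteinChange[i]))
    paste(parts, collapse = ";")
  }, character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$chrom,
                  as.integer(calls$pos), calls$ref, calls$alt, info)
  writeLines(c(header, body), path)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A [SyntheticCohort-class] equal (up to numeric round-trip) to
#'   the one written.
#' @export
readCohort <- function(dir) {
  rt <- function(name, ...) utils::read.table(
    file.path(dir, name), sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE, ...)
  counts <- rt("expression.tsv")
  rownames(counts) <- counts$gene
  counts$gene <- NULL
  counts <- as.matrix(counts)
  labels <- rt("sample_labels.tsv")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(labels, row.names = labels$sample))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  vcfDir <- file.path(dir, "vcf")
  variants <- data.frame()
  if (dir.exists(vcfDir)) {
    vfiles <- list.files(vcfDir, pattern = "\\.vcf$", full.names = TRUE)
    parsed <- lapply(vfiles, function(f) {
      stem <- sub("\\.vcf$", "", basename(f))
      parts <- strsplit(stem, "_")[[1]]
      caller <- parts[length(parts)]
      sid <- paste(parts[-length(parts)], collapse = "_")
      readPlainVcf(f, caller = caller, sample = sid)
    })
    variants <- do.call(rbind, parsed)
    rownames(variants) <- NULL
  }
  methods::new("SyntheticCohort", expression = se, variants = variants,
               segments = rt("segments.tsv"), bins = rt("bins.tsv"),
               purityPloidy = rt("purity_ploidy.tsv"),
               clinical = rt("clinical.tsv"), truth = truth)
}

## dependency-light VCF reader for files written by writeSimpleVcf
readPlainVcf <- function(path, caller, sample) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame())
  f <- strsplit(body, "\t")
  getInfo <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[^;]+"), info,
                                  perl = TRUE))
    if (length(m)) m else NA_character_
  }
  do.call(rbind, lapply(f, function(x) {
    data.frame(sample = sample, chrom = x[1], pos = as.integer(x[2]),
               ref = x[4], alt = x[5], caller = caller,
               baseq = as.numeric(getInfo(x[8], "BQ")),
               strandBias = grepl("(^|;)SB(;|$)", x[8]),
               gene = getInfo(x[8], "GENE"),
               proteinChange = getInfo(x[8], "PCHANGE"),
               stringsAsFactors = FALSE)
  }))
}
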