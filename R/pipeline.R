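## Pipeline orchestration: schema-validated configuration, an end-to-end
## run over a synthetic (or user-supplied) cohort, and the embedded
## reference contingency checks.

pipelineSchema <- function() {
  list(
    source = list(type = "character", required = TRUE,
                  allowed = c("synthetic")),
    seed = list(type = "numeric", required = TRUE, min = 0),
    nPatients = list(type = "numeric", required = FALSE, min = 2),
    outputDir = list(type = "character", required = FALSE),
    captureMb = list(type = "numeric", required = FALSE, min = 1e-6),
    minBaseq = list(type = "numeric", required = FALSE, min = 0),
    clusterKRange = list(type = "numeric", required = FALSE),
    referenceChecks = list(type = "logical", required = FALSE))
}

#' Validate a pipeline configuration
#'
#' Checks a configuration document (a named list, or a YAML/JSON file
#' path) against the pipeline schema: unknown keys are rejected, types
#' checked, required keys enforced, and defaults filled. All violations
#' are collected and reported together.
#'
#' @param config Named list, or path to a YAML or JSON document.
#' @return The validated configuration with defaults filled.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list", call. = FALSE)
  schema <- pipelineSchema()
  errors <- character(0)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  for (key in names(schema)) {
    rule <- schema[[key]]
    if (!key %in% names(config)) {
      if (rule$required) errors <- c(errors,
                                     paste0("missing required key: ", key))
      next
    }
    val <- config[[key]]
    ok <- switch(rule$type, numeric = is.numeric(val),
                 character = is.character(val), logical = is.logical(val))
    if (!ok) {
      errors <- c(errors, sprintf("key '%s' must be %s", key, rule$type))
      next
    }
    if (!is.null(rule$min) && any(val < rule$min))
      errors <- c(errors, sprintf("key '%s' must be >= %s", key,
                                  format(rule$min)))
    if (!is.null(rule$allowed) && !all(val %in% rule$allowed))
      errors <- c(errors, sprintf("key '%s' must be one of: %s", key,
                                  paste(rule$allowed, collapse = ", ")))
  }
  if (length(errors))
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  defaults <- list(nPatients = 92, captureMb = 50, minBaseq = 30,
                   clusterKRange = 2:5, referenceChecks = FALSE)
  for (key in names(defaults))
    if (is.null(config[[key]])) config[[key]] <- defaults[[key]]
  config
}

#' Reference cohort contingency checks
#'
#' Re-computes the four cohort-level contingency tests on tables
#' reconstructed from published group sizes and percentages of a Mexican
#' acral-melanoma cohort (85 patients with analysable primaries: 42 with
#' a driver mutation, 43 quadruple wild type; 44 patients in three
#' transcriptional clusters of sizes 14, 16 and 14). No input files are
#' required.
#'
#' @return list of `acroTest` results: Pearson chi-squared on
#'   recurrence-by-driver and death-by-driver (2 x 2) and
#'   death-by-cluster (3 x 2), and the Freeman-Halton exact test on
#'   recurrence-by-cluster (3 x 2).
#' @export
referenceChecks <- function() {
  recurrenceByDriver <- matrix(c(28, 16, 14, 27), 2,
                               dimnames = list(c("mutated", "QWT"),
                                               c("recurred", "not")))
  deathByDriver <- matrix(c(11, 4, 31, 39), 2,
                          dimnames = list(c("mutated", "QWT"),
                                          c("died", "alive")))
  deathByCluster <- matrix(c(0, 7, 3, 14, 9, 11), 3,
                           dimnames = list(paste0("cluster", 1:3),
                                           c("died", "alive")))
  recurrenceByCluster <- matrix(c(5, 13, 8, 9, 3, 6), 3,
                                dimnames = list(paste0("cluster", 1:3),
                                                c("recurred", "not")))
  list(recurrenceByDriver = pearsonChi2(recurrenceByDriver),
       deathByDriver = pearsonChi2(deathByDriver),
       deathByCluster = pearsonChi2(deathByCluster),
       recurrenceByCluster = fisherExactRxC(recurrenceByCluster))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, then runs the stages in dependency
#' order: variant consensus and driver profiling, copy-number QC, burden
#' and homozygous-deletion calling, origin-score training and scoring,
#' consensus clustering with signature analysis, and the association and
#' survival statistics. All randomness flows from `config$seed` via the
#' documented child-seed scheme, so two runs with the same configuration
#' produce identical reports (apart from timestamps).
#'
#' @param config A configuration accepted by [validateConfig()].
#' @return A list report; if `config$outputDir` is set, the report is also
#'   written there as JSON together with the stage tables.
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  t0 <- Sys.time()
  seed <- as.integer(config$seed)
  simCfg <- defaultSimConfig(nPatients = config$nPatients)
  cohort <- simulateCohort(simCfg, seed = seed)
  clin <- cohortClinical(cohort)

  ## --- variants -> driver profiles
  calls <- filterQuality(cohortVariants(cohort),
                         minBaseq = config$minBaseq)
  consensus <- mergeCallers(calls,
                            callers = simCfg$variants$callers)
  sampleMeta <- data.frame(patient = sub("-.*", "", consensus$sample),
                           sample = consensus$sample,
                           stringsAsFactors = FALSE)
  sampleMeta <- unique(sampleMeta)
  sampleMeta$type <- ifelse(grepl("-T", sampleMeta$sample), "primary",
                            "metastasis")
  ## patients with no calls still need a profile row
  allMeta <- data.frame(patient = clin$patient,
                        sample = paste0(clin$patient, "-T1"),
                        type = "primary", stringsAsFactors = FALSE)
  sampleMeta <- unique(rbind(sampleMeta, allMeta))
  profiles <- driverProfiles(consensus, sampleMeta,
                             captureSizeMb = config$captureMb)

  ## --- copy number
  qc <- purityQC(cohortPurityPloidy(cohort))
  passed <- qc$sample[qc$status == "pass"]
  segs <- cohortSegments(cohort)
  burden <- computeBurden(segs[segs$sample %in% passed, ])
  pp <- cohortPurityPloidy(cohort)
  bins <- cohortBins(cohort)
  hdCfg <- simCfg$cna$homdelGenes
  homdels <- do.call(rbind, lapply(passed, function(s) {
    rho <- pp$purityA[pp$sample == s]; psi <- pp$ploidy[pp$sample == s]
    thr <- homdelThreshold(rho, psi)
    do.call(rbind, lapply(seq_len(nrow(hdCfg)), function(h) {
      b <- bins[bins$sample == s & bins$region == hdCfg$gene[h], ]
      call <- callHomozygousDeletion(
        b, thr, list(chrom = hdCfg$chrom[h], start = hdCfg$start[h],
                     end = hdCfg$end[h]), rule = hdCfg$rule[h])
      data.frame(sample = s, gene = hdCfg$gene[h], status = call$status,
                 stringsAsFactors = FALSE)
    }))
  }))

  ## --- origin score (panel trained on a two-lineage training set)
  trainLabels <- data.frame(
    sample = sprintf("TR%02d", 1:20),
    class = rep(c("acral", "cutaneous"), each = 10),
    cluster = NA_integer_, braf = FALSE, stringsAsFactors = FALSE)
  trainSim <- simulateExpression(trainLabels, simCfg$expression,
                                 seed = childSeed(seed, 20))
  hk <- trainSim$genes$housekeeping
  trainNorm <- normalizeCounts(round(trainSim$counts), hk)
  panel <- trainPanel(trainNorm$log2, trainLabels$class)
  se <- cohortExpression(cohort)
  cohortNorm <- normalizeCounts(
    round(SummarizedExperiment::assay(se, "counts")), hk)
  scores <- acScore(cohortNorm$log2, panel)
  braf <- SummarizedExperiment::colData(se)$braf
  scoreTest <- if (length(unique(braf)) == 2)
    compareScores(scores, factor(ifelse(braf, "BRAF", "WT"),
                                 levels = c("BRAF", "WT")),
                  alternative = "less") else NULL

  ## --- consensus clustering + signatures
  mat <- preprocessMatrix(cohortNorm$log2)
  cc <- consensusPartition(mat, kRange = config$clusterKRange,
                           seed = childSeed(seed, 30))
  labs <- clusterLabels(cc)
  sig <- signatureGenes(mat, labs)
  sigGenes <- sig$gene[sig$significant]
  modules <- if (length(sigGenes) >= 3)
    geneModules(mat[sigGenes, , drop = FALSE], labs,
                seed = childSeed(seed, 31)) else NULL

  ## --- statistics
  clin2 <- merge(clin, profiles, by = "patient")
  X <- cbind(mutated = clin2$mutated,
             advancedStage = clin2$advancedStage,
             age = clin2$age)
  recurrenceFit <- logisticFit(X, clin2$recurrence)
  coxFit <- coxphFit(clin2$timeDeath, clin2$death,
                     X[, c("mutated", "age")])
  lr <- logrankTest(clin2$timeDeath, clin2$death, clin2$mutated)
  km <- kmEstimate(clin2$timeRecurrence, clin2$recurrence)
  gcsTmb <- {
    m <- merge(burden, data.frame(sample = profiles$indexSample,
                                  tmb = profiles$tmb), by = "sample")
    if (nrow(m) >= 3 && stats::sd(m$gcs) > 0 && stats::sd(m$tmb) > 0)
      pearsonCorrelation(m$gcs, m$tmb) else NULL
  }

  report <- list(
    parameters = config, seed = seed, nPatients = config$nPatients,
    driverTable = table(profiles$category),
    tmbMean = mean(profiles$tmb),
    purityQC = table(qc$status),
    burden = burden, homdels = homdels,
    panel = list(acral = acralGenes(panel),
                 cutaneous = cutaneousGenes(panel),
                 component = panelComponent(panel)),
    scores = scores, scoreTest = scoreTest,
    clustering = list(chosen = chosenPartition(cc),
                      metrics = stabilityMetrics(cc),
                      labels = labs),
    nSignatureGenes = length(sigGenes),
    modules = if (!is.null(modules)) moduleMembers(modules) else NULL,
    recurrenceModel = recurrenceFit, coxModel = coxFit, logrank = lr,
    kmRecurrence = km, gcsTmbCorrelation = gcsTmb,
    referenceChecks = if (isTRUE(config$referenceChecks))
      referenceChecks() else NULL,
    version = as.character(utils::packageVersion("acrotype")),
    wallTimeSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    keep <- report[c("parameters", "seed", "nPatients", "tmbMean",
                     "nSignatureGenes", "version")]
    jsonlite::write_json(keep, file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(report$burden,
                       file.path(config$outputDir, "burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$scores,
                       file.path(config$outputDir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
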