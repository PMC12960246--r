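## Multi-caller somatic variant consensus: merge calls under a 2-of-3 rule
## with a protein-change rescue list, base-quality and strand-bias
## filtering, index-sample selection, driver classification and TMB.
##
## Calls are plain data.frames with columns: sample, chrom, pos (1-based),
## ref, alt, caller, and optionally baseq (Phred), strandBias (logical),
## gene, proteinChange, filter.

DRIVER_GENES <- c("BRAF", "NRAS", "KIT", "NF1")

## trim the shared prefix, then the shared suffix, of ref/alt (always
## keeping at least one base), adjusting pos; this canonicalizes redundant
## indel representations between callers (full left-alignment would need
## the reference sequence and is out of scope).
normalizeAllele <- function(chrom, pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

normalizeRescueKey <- function(gene, proteinChange) {
  pc <- toupper(sub("^P\\.", "", toupper(trimws(proteinChange))))
  paste0(toupper(trimws(gene)), ":", pc)
}

parseRescueList <- function(rescue) {
  parts <- strsplit(rescue, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2) stop("rescue entries must be 'GENE:p.CHANGE'",
                             call. = FALSE)
    normalizeRescueKey(p[1], p[2])
  }, character(1))
}

#' Merge per-caller somatic calls into a consensus set
#'
#' A site (keyed by sample, chrom, pos, ref, alt after indel trimming) is
#' retained when called by at least `minCallers` of the declared callers,
#' or when called by at least one caller and its gene + protein change
#' matches an entry of the rescue list (default: BRAF p.V600E, whose
#' oncogenicity in melanoma justifies single-caller retention). The
#' supporting caller set is kept as provenance. Adding a caller's support
#' to a site can never remove it from the consensus, and the merge is
#' independent of input order.
#'
#' @param calls data.frame of per-caller calls (see file header).
#' @param callers Character vector of declared caller ids; defaults to the
#'   callers present in `calls`. Exactly three are expected unless
#'   `allowAnyCallerCount = TRUE`.
#' @param rescue Character vector of `"GENE:p.CHANGE"` rescue entries.
#' @param minCallers Consensus threshold (default 2).
#' @param allowAnyCallerCount Override for the three-caller check.
#' @return data.frame of consensus calls with `callers` (comma-separated
#'   provenance), `nCallers` and `rescued` columns.
#' @export
mergeCallers <- function(calls, callers = NULL,
                         rescue = "BRAF:p.V600E", minCallers = 2,
                         allowAnyCallerCount = FALSE) {
  if (is.null(callers)) callers <- sort(unique(calls$caller))
  if (length(callers) != 3 && !allowAnyCallerCount)
    stop("expected exactly 3 declared callers (got ", length(callers),
         "); set allowAnyCallerCount = TRUE to override", call. = FALSE)
  if (!all(calls$caller %in% callers))
    stop("calls from undeclared caller(s): ",
         paste(setdiff(unique(calls$caller), callers), collapse = ", "),
         call. = FALSE)
  if (any(calls$ref == calls$alt))
    stop("ref and alt must differ", call. = FALSE)
  norm <- Map(normalizeAllele, calls$chrom, calls$pos, calls$ref, calls$alt)
  calls$pos <- vapply(norm, `[[`, numeric(1), "pos")
  calls$ref <- vapply(norm, `[[`, character(1), "ref")
  calls$alt <- vapply(norm, `[[`, character(1), "alt")
  key <- paste(calls$sample, calls$chrom, calls$pos, calls$ref, calls$alt,
               sep = "\r")
  if (anyDuplicated(paste(key, calls$caller, sep = "\r")))
    stop("duplicate (caller, site) record", call. = FALSE)
  rescueKeys <- if (length(rescue)) parseRescueList(rescue) else character(0)
  keep <- vapply(split(seq_len(nrow(calls)), key), function(idx) {
    n <- length(idx)
    if (n >= minCallers) return(idx[1])
    row <- calls[idx[1], ]
    if (length(rescueKeys) && !is.null(row$gene) &&
        !is.null(row$proteinChange) && !is.na(row$gene) &&
        !is.na(row$proteinChange) &&
        normalizeRescueKey(row$gene, row$proteinChange) %in% rescueKeys)
      return(idx[1])
    NA_integer_
  }, integer(1))
  support <- vapply(split(calls$caller, key), function(cc)
    paste(sort(cc), collapse = ","), character(1))
  nSupport <- vapply(split(calls$caller, key), length, integer(1))
  ok <- !is.na(keep)
  out <- calls[keep[ok], setdiff(names(calls), "caller"), drop = FALSE]
  out$callers <- support[ok]
  out$nCallers <- nSupport[ok]
  out$rescued <- out$nCallers < minCallers
  out <- out[order(out$sample, out$chrom, out$pos, out$ref, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Filter calls on base quality and strand bias
#'
#' Calls with Phred base quality below `minBaseq` are removed (the
#' boundary is an inclusive keep: quality exactly `minBaseq` is retained);
#' calls flagged as strand-biased are removed when `dropStrandBias` is
#' set. A missing base quality or strand-bias flag is treated as
#' passing — callers without these annotations are not penalized.
#'
#' @param calls data.frame with optional `baseq` and `strandBias` columns.
#' @param minBaseq Minimum Phred base quality (default 30).
#' @param dropStrandBias Remove strand-bias-flagged calls (default TRUE).
#' @return Filtered data.frame; removal counts in
#'   `attr(, "filterCounts")`.
#' @export
filterQuality <- function(calls, minBaseq = 30, dropStrandBias = TRUE) {
  if (minBaseq < 0) stop("negative base-quality threshold", call. = FALSE)
  lowQ <- if ("baseq" %in% names(calls))
    !is.na(calls$baseq) & calls$baseq < minBaseq else rep(FALSE, nrow(calls))
  biased <- if (dropStrandBias && "strandBias" %in% names(calls))
    !is.na(calls$strandBias) & calls$strandBias else rep(FALSE, nrow(calls))
  out <- calls[!lowQ & !biased, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filterCounts") <- c(lowBaseq = sum(lowQ),
                                 strandBias = sum(biased & !lowQ))
  out
}

#' Select one index sample per patient
#'
#' Primaries are preferred; metastases or recurrences are chosen only when
#' no primary exists. Within a type, ties break deterministically by
#' earlier collection date, then lexicographic sample id.
#'
#' @param samples data.frame with columns `patient`, `sample`, `type`
#'   (one of primary/metastasis/recurrence/other) and optionally
#'   `collectionDate`.
#' @return data.frame with one row per patient (`patient`, `sample`).
#' @export
selectIndexSample <- function(samples) {
  stopifnot(all(c("patient", "sample", "type") %in% names(samples)))
  if (!nrow(samples)) stop("patient with zero samples", call. = FALSE)
  prio <- c(primary = 1, metastasis = 2, recurrence = 3, other = 4)
  p <- prio[match(samples$type, names(prio))]
  if (any(is.na(p))) stop("unknown sample type(s): ",
                          paste(unique(samples$type[is.na(p)]),
                                collapse = ", "), call. = FALSE)
  dt <- if ("collectionDate" %in% names(samples))
    as.numeric(as.Date(samples$collectionDate)) else rep(0, nrow(samples))
  picked <- vapply(split(seq_len(nrow(samples)), samples$patient),
                   function(idx) {
    o <- order(p[idx], dt[idx], samples$sample[idx])
    idx[o[1]]
  }, integer(1))
  out <- samples[picked, c("patient", "sample")]
  rownames(out) <- NULL
  out
}

#' Classify a patient's driver category
#'
#' `multi-hit` when two or more distinct driver genes are mutated, the
#' single mutated gene's name when exactly one is, and `QWT` (quadruple
#' wild type) when none of BRAF, NRAS, KIT and NF1 carries a mutation.
#'
#' @param variants Consensus variant data.frame for one patient, with a
#'   `gene` column.
#' @param driverGenes Character vector (default BRAF, NRAS, KIT, NF1).
#' @return A single character string.
#' @export
classifyDriverStatus <- function(variants, driverGenes = DRIVER_GENES) {
  if (nrow(variants) && !"gene" %in% names(variants))
    stop("variants must carry gene annotation", call. = FALSE)
  hit <- unique(variants$gene[variants$gene %in% driverGenes])
  if (length(hit) == 0) "QWT"
  else if (length(hit) == 1) hit
  else "multi-hit"
}

#' Tumour mutational burden
#'
#' SNVs plus indels per megabase of captured territory.
#'
#' @param variants Consensus variant data.frame (one row per variant).
#' @param captureSizeMb Capture size in megabases (> 0).
#' @return Mutations per megabase.
#' @export
computeTmb <- function(variants, captureSizeMb) {
  assertScalar(captureSizeMb, "captureSizeMb")
  if (captureSizeMb <= 0) stop("captureSizeMb must be > 0", call. = FALSE)
  nrow(variants) / captureSizeMb
}

#' Per-patient driver profiles from consensus calls
#'
#' Applies index-sample selection, then classifies each patient's driver
#' category and computes TMB from the index sample's consensus variants.
#'
#' @param consensus Consensus calls (from [mergeCallers()]).
#' @param samples Sample metadata as in [selectIndexSample()].
#' @param captureSizeMb Capture size for TMB.
#' @return data.frame: `patient`, `indexSample`, `category`, `nVariants`,
#'   `tmb`.
#' @export
driverProfiles <- function(consensus, samples, captureSizeMb = 50) {
  idx <- selectIndexSample(samples)
  res <- lapply(seq_len(nrow(idx)), function(i) {
    v <- consensus[consensus$sample == idx$sample[i], , drop = FALSE]
    data.frame(patient = idx$patient[i], indexSample = idx$sample[i],
               category = classifyDriverStatus(v), nVariants = nrow(v),
               tmb = computeTmb(v, captureSizeMb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read one caller's VCF into the package call format
#'
#' Thin wrapper over `VariantAnnotation::readVcf`; keeps PASS (and
#' missing-FILTER) records by default, expands the first ALT allele, and
#' pulls optional BQ / SB / GENE / PCHANGE INFO fields when present.
#'
#' @param path VCF file path.
#' @param caller Caller id to stamp on the records.
#' @param sample Sample id (defaults to the VCF sample name or file stem).
#' @param passOnly Keep only FILTER == PASS / "." records (default TRUE).
#' @return data.frame in the package call format.
#' @export
readCallerVcf <- function(path, caller, sample = NULL, passOnly = TRUE) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF files", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  filt <- as.character(rr$FILTER)
  keep <- if (passOnly) filt %in% c("PASS", ".", "") else
    rep(TRUE, length(rr))
  info <- VariantAnnotation::info(vcf)
  getInfo <- function(field) {
    if (field %in% colnames(info)) {
      v <- info[[field]]
      if (is(v, "List")) v <- vapply(v, function(x)
        if (length(x)) as.character(x[[1]]) else NA_character_,
        character(1))
      as.vector(v)
    } else rep(NA, length(rr))
  }
  alt <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                function(a) if (length(a)) a[[1]] else NA_character_,
                character(1))
  smp <- sample %||% (if (length(colnames(vcf))) colnames(vcf)[1] else
    sub("\\.vcf$", "", basename(path)))
  out <- data.frame(
    sample = smp,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    caller = caller,
    baseq = suppressWarnings(as.numeric(getInfo("BQ"))),
    strandBias = as.logical(getInfo("SB")),
    gene = as.character(getInfo("GENE")),
    proteinChange = as.character(getInfo("PCHANGE")),
    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}
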