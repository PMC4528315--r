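#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
NULL

#' Simulation configuration
#'
#' Holds every tunable of the synthetic-data generator: genome composition,
#' TRIM element dimensions, the molecular clock, and the sequencing regime.
#' The seed fully determines all generator output.
#'
#' @slot seed integer; master RNG seed.
#' @slot chromosomeLengths integer vector of chromosome lengths (bp).
#' @slot gcContent background GC fraction in [0, 1].
#' @slot ltrLength LTR length in bp (default 230).
#' @slot internalLength internal-domain length in bp (default 72).
#' @slot tsdLength target-site-duplication length in bp (default 5).
#' @slot substitutionRate per-site, per-year substitution rate r
#'   (default 1.3e-8), used both to age planted LTR pairs and, downstream,
#'   to convert divergence back to time via T = K/(2r).
#' @slot tsTvRatio transition/transversion rate ratio of the aging model
#'   (total transition rate over total transversion rate; default 2).
#' @slot readLength read length in bp (default 150).
#' @slot insertSizeMean,insertSizeSd fragment-size distribution (bp).
#' @slot coverage fold sequencing coverage (default 5).
#' @slot errorRate per-base substitution error rate in [0, 1).
#' @slot groupSizes integer vector, accessions per germplasm group.
#' @slot nFixedSites,nGroupPrivateSites,nLinePrivateSites counts of
#'   panel-wide, group-private, and line-private polymorphic insertion sites.
#' @exportClass TrimSimConfig
setClass("TrimSimConfig",
  representation(
    seed = "integer",
    chromosomeLengths = "integer",
    gcContent = "numeric",
    ltrLength = "integer",
    internalLength = "integer",
    tsdLength = "integer",
    substitutionRate = "numeric",
    tsTvRatio = "numeric",
    readLength = "integer",
    insertSizeMean = "numeric",
    insertSizeSd = "numeric",
    coverage = "numeric",
    errorRate = "numeric",
    groupSizes = "integer",
    nFixedSites = "integer",
    nGroupPrivateSites = "integer",
    nLinePrivateSites = "integer"
  )
)

setValidity("TrimSimConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@chromosomeLengths) < 1L ||
      any(object@chromosomeLengths <= 0L))
    msg <- c(msg, "chromosome lengths must be positive")
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "gcContent must lie in [0, 1]")
  for (s in c("ltrLength", "internalLength", "readLength")) {
    if (slot(object, s) <= 0L) msg <- c(msg, paste(s, "must be positive"))
  }
  if (object@tsdLength < 0L) msg <- c(msg, "tsdLength must be >= 0")
  if (object@coverage < 0) msg <- c(msg, "coverage must be >= 0")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must lie in [0, 1)")
  if (object@substitutionRate <= 0)
    msg <- c(msg, "substitutionRate must be positive")
  if (object@insertSizeMean < object@readLength)
    msg <- c(msg, "insertSizeMean must be >= readLength")
  if (length(msg)) msg else TRUE
})

#' TRIM consensus element
#'
#' The sequence of a consensus TRIM together with its component map:
#' 5' LTR, internal domain, 3' LTR, and the planted PBS/PPT motifs.
#' All component coordinates are 1-based within \code{sequence}.
#'
#' @slot sequence a \code{DNAString}, 5'LTR + internal + 3'LTR.
#' @slot ltr5,internal,ltr3,pbs,ppt \code{IRanges} component coordinates.
#' @exportClass TrimConsensus
setClass("TrimConsensus",
  representation(
    sequence = "DNAString",
    ltr5 = "IRanges",
    internal = "IRanges",
    ltr3 = "IRanges",
    pbs = "IRanges",
    ppt = "IRanges"
  )
)

#' TRIM search model
#'
#' Consensus sequences and thresholds used by the genome scanner.
#'
#' @slot ltrConsensus,internalConsensus \code{DNAString} consensus sequences.
#' @slot tsdLength expected TSD length (default 5).
#' @slot minIdentity minimum alignment identity for a hit (default 0.80).
#' @slot minCoverage minimum consensus coverage for a hit (default 0.80).
#' @exportClass TrimModel
setClass("TrimModel",
  representation(
    ltrConsensus = "DNAString",
    internalConsensus = "DNAString",
    tsdLength = "integer",
    minIdentity = "numeric",
    minCoverage = "numeric"
  )
)

setValidity("TrimModel", function(object) {
  msg <- character()
  if (length(object@ltrConsensus) == 0L)
    msg <- c(msg, "ltrConsensus must be non-empty")
  if (length(object@internalConsensus) == 0L)
    msg <- c(msg, "internalConsensus must be non-empty")
  if (object@minIdentity <= 0 || object@minIdentity > 1)
    msg <- c(msg, "minIdentity must lie in (0, 1]")
  if (object@minCoverage <= 0 || object@minCoverage > 1)
    msg <- c(msg, "minCoverage must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' A simulated genome with its ground truth
#'
#' @slot genome \code{DNAStringSet}, one record per chromosome.
#' @slot elements \code{GRanges} of planted elements in emitted-genome
#'   coordinates, with metadata columns \code{category}, \code{age_years},
#'   \code{tsd}, \code{ltr_count}, \code{insertion_point} (0-based offset in
#'   the pre-insertion sequence), and \code{nested} (nested-insertion interval
#'   as "start-end" or NA).
#' @slot consensus the \code{TrimConsensus} the elements derive from.
#' @slot config the \code{TrimSimConfig} used.
#' @exportClass TrimSimulation
setClass("TrimSimulation",
  representation(
    genome = "DNAStringSet",
    elements = "GRanges",
    consensus = "TrimConsensus",
    config = "TrimSimConfig"
  )
)

#' A simulated accession panel
#'
#' @slot reference the \code{TrimSimulation} reference genome.
#' @slot accessionGenomes named list of \code{DNAStringSet}, one per accession.
#' @slot groups named character vector, accession -> germplasm group.
#' @slot sites data.frame of polymorphic/fixed insertion sites: \code{site_id},
#'   \code{chrom}, \code{pos} (0-based insertion offset in reference
#'   coordinates), \code{class}, \code{tsd}.
#' @slot genotypes integer truth matrix (accessions x sites, 1 = carrier).
#' @exportClass TrimPanel
setClass("TrimPanel",
  representation(
    reference = "TrimSimulation",
    accessionGenomes = "list",
    groups = "character",
    sites = "data.frame",
    genotypes = "matrix"
  )
)

#' Presence/absence/missing genotype matrix
#'
#' Accessions x sites matrix over {present, absent, missing}; internally
#' presence is 1L, absence 0L, missing NA. Read support behind each call is
#' retained.
#'
#' @slot values integer matrix (1/0/NA).
#' @slot supportPresent,supportAbsent integer matrices of junction-read counts.
#' @slot conflict logical matrix; TRUE where both alleles had read support and
#'   the cell was therefore set to missing.
#' @exportClass PAVMatrix
setClass("PAVMatrix",
  representation(
    values = "matrix",
    supportPresent = "matrix",
    supportAbsent = "matrix",
    conflict = "matrix"
  )
)

setValidity("PAVMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.integer(v)) msg <- c(msg, "values must be an integer matrix")
  if (!all(v %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "values must be 1, 0 or NA")
  for (s in c("supportPresent", "supportAbsent", "conflict")) {
    if (!identical(dim(slot(object, s)), dim(v)))
      msg <- c(msg, paste(s, "dimensions must match values"))
  }
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry accession rownames and site colnames")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrimSimConfig-class compact display
#' @param object a \code{TrimSimConfig}
#' @export
setMethod("show", "TrimSimConfig", function(object) {
  cat("TrimSimConfig | seed:", object@seed,
      "| genome:", paste(object@chromosomeLengths, collapse = "+"), "bp",
      "| LTR:", object@ltrLength, "bp | internal:", object@internalLength,
      "bp | TSD:", object@tsdLength, "bp\n")
  cat("  r:", format(object@substitutionRate), "subs/site/yr | ts/tv:",
      object@tsTvRatio, "| reads:", object@readLength, "bp @",
      object@coverage, "x, err", object@errorRate, "\n")
  cat("  panel:", paste(object@groupSizes, collapse = "/"),
      "accessions per group |", object@nFixedSites, "fixed +",
      object@nGroupPrivateSites, "group-private +",
      object@nLinePrivateSites, "line-private sites\n")
})

#' @describeIn TrimConsensus-class compact display
#' @param object a \code{TrimConsensus}
#' @export
setMethod("show", "TrimConsensus", function(object) {
  cat("TrimConsensus of", length(object@sequence), "bp:",
      "LTRs", IRanges::width(object@ltr5), "bp, internal",
      IRanges::width(object@internal), "bp\n")
})

#' @describeIn TrimSimulation-class compact display
#' @param object a \code{TrimSimulation}
#' @export
setMethod("show", "TrimSimulation", function(object) {
  cat("TrimSimulation:", length(object@genome), "chromosome(s),",
      sum(Biostrings::width(object@genome)), "bp total;",
      length(object@elements), "planted element(s)\n")
  if (length(object@elements))
    print(table(category = object@elements$category))
})

#' @describeIn TrimPanel-class compact display
#' @param object a \code{TrimPanel}
#' @export
setMethod("show", "TrimPanel", function(object) {
  cat("TrimPanel:", length(object@accessionGenomes), "accessions in",
      length(unique(object@groups)), "groups;",
      nrow(object@sites), "insertion sites (",
      paste(names(table(object@sites$class)), table(object@sites$class),
            sep = "=", collapse = ", "), ")\n")
})

#' @describeIn PAVMatrix-class compact display
#' @param object a \code{PAVMatrix}
#' @export
setMethod("show", "PAVMatrix", function(object) {
  v <- object@values
  cat("PAVMatrix:", nrow(v), "accessions x", ncol(v), "sites |",
      sum(v == 1L, na.rm = TRUE), "present,",
      sum(v == 0L, na.rm = TRUE), "absent,",
      sum(is.na(v)), "missing\n")
})
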