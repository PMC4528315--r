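## Constructors and accessor functions for the S4 containers.

#' Create a simulation configuration
#'
#' Defaults follow the TRIM family the package models: 230-bp LTRs, a 72-bp
#' internal domain (total 532 bp), 5-bp TSDs, and a molecular clock of
#' r = 1.3e-8 substitutions per site per year. Sequencing defaults emulate a
#' short-read resequencing panel: 150-bp paired reads at 5x coverage.
#'
#' @param seed master RNG seed (mandatory; fully determines output).
#' @param chromosomeLengths integer vector of chromosome lengths in bp.
#' @param gcContent background GC fraction.
#' @param ltrLength,internalLength,tsdLength element dimensions in bp.
#' @param substitutionRate per-site per-year substitution rate r.
#' @param tsTvRatio transition/transversion rate ratio for LTR aging.
#' @param readLength,insertSizeMean,insertSizeSd,coverage,errorRate
#'   sequencing regime.
#' @param groupSizes accessions per germplasm group.
#' @param nFixedSites,nGroupPrivateSites,nLinePrivateSites polymorphic-site
#'   class counts for the accession panel.
#' @return a validated \code{\linkS4class{TrimSimConfig}}.
#' @examples
#' cfg <- trimSimConfig(seed = 1, chromosomeLengths = c(20000, 20000))
#' cfg
#' @export
trimSimConfig <- function(seed,
                          chromosomeLengths = c(50000L, 50000L),
                          gcContent = 0.46,
                          ltrLength = 230L,
                          internalLength = 72L,
                          tsdLength = 5L,
                          substitutionRate = 1.3e-8,
                          tsTvRatio = 2,
                          readLength = 150L,
                          insertSizeMean = 400,
                          insertSizeSd = 40,
                          coverage = 5,
                          errorRate = 0.002,
                          groupSizes = c(modern = 4L, landrace = 4L,
                                         teosinte = 4L),
                          nFixedSites = 5L,
                          nGroupPrivateSites = 6L,
                          nLinePrivateSites = 4L) {
  if (missing(seed)) stop("a seed is mandatory")
  gs <- as.integer(groupSizes)
  names(gs) <- if (is.null(names(groupSizes)))
    paste0("group", seq_along(groupSizes)) else names(groupSizes)
  new("TrimSimConfig",
      seed = as.integer(seed),
      chromosomeLengths = as.integer(chromosomeLengths),
      gcContent = gcContent,
      ltrLength = as.integer(ltrLength),
      internalLength = as.integer(internalLength),
      tsdLength = as.integer(tsdLength),
      substitutionRate = substitutionRate,
      tsTvRatio = tsTvRatio,
      readLength = as.integer(readLength),
      insertSizeMean = insertSizeMean,
      insertSizeSd = insertSizeSd,
      coverage = coverage,
      errorRate = errorRate,
      groupSizes = gs,
      nFixedSites = as.integer(nFixedSites),
      nGroupPrivateSites = as.integer(nGroupPrivateSites),
      nLinePrivateSites = as.integer(nLinePrivateSites))
}

#' Create a TRIM search model
#'
#' @param ltrConsensus,internalConsensus consensus sequences
#'   (\code{DNAString} or character).
#' @param tsdLength expected TSD length in bp.
#' @param minIdentity minimum alignment identity of a reported hit. The
#'   default 0.80 admits the >= 90\% within-family identity typical of young
#'   TRIM families while leaving headroom for older copies.
#' @param minCoverage minimum fraction of the consensus a hit must cover.
#' @return a \code{\linkS4class{TrimModel}}.
#' @export
trimModel <- function(ltrConsensus, internalConsensus, tsdLength = 5L,
                      minIdentity = 0.80, minCoverage = 0.80) {
  new("TrimModel",
      ltrConsensus = as(ltrConsensus, "DNAString"),
      internalConsensus = as(internalConsensus, "DNAString"),
      tsdLength = as.integer(tsdLength),
      minIdentity = minIdentity,
      minCoverage = minCoverage)
}

#' Derive the search model from a consensus element
#'
#' @param consensus a \code{\linkS4class{TrimConsensus}}.
#' @param ... passed to \code{\link{trimModel}}.
#' @export
asTrimModel <- function(consensus, ...) {
  trimModel(ltrConsensus = consensusLTR(consensus),
            internalConsensus = consensusInternal(consensus), ...)
}

#' @rdname TrimConsensus-class
#' @param x a \code{TrimConsensus}
#' @export
consensusSequence <- function(x) x@sequence

#' @rdname TrimConsensus-class
#' @export
consensusLTR <- function(x) Biostrings::subseq(x@sequence, IRanges::start(x@ltr5),
                                               IRanges::end(x@ltr5))

#' @rdname TrimConsensus-class
#' @export
consensusInternal <- function(x)
  Biostrings::subseq(x@sequence, IRanges::start(x@internal),
                     IRanges::end(x@internal))

#' @rdname TrimSimulation-class
#' @param x a \code{TrimSimulation}
#' @export
simGenome <- function(x) x@genome

#' @rdname TrimSimulation-class
#' @export
simElements <- function(x) x@elements

#' @rdname TrimSimulation-class
#' @export
simConsensus <- function(x) x@consensus

#' @rdname TrimSimulation-class
#' @export
simConfig <- function(x) x@config

#' @rdname TrimPanel-class
#' @param x a \code{TrimPanel}
#' @export
panelReference <- function(x) x@reference

#' @rdname TrimPanel-class
#' @export
panelGenomes <- function(x) x@accessionGenomes

#' @rdname TrimPanel-class
#' @export
panelGroups <- function(x) x@groups

#' @rdname TrimPanel-class
#' @export
panelSites <- function(x) x@sites

#' @rdname TrimPanel-class
#' @export
panelGenotypes <- function(x) x@genotypes

#' Construct a PAV matrix
#'
#' @param values integer matrix over 1/0/NA with accession rownames and site
#'   colnames. Character matrices over "1"/"0"/"?" are converted.
#' @param supportPresent,supportAbsent,conflict optional matrices of matching
#'   dimensions; zero/FALSE matrices are used when omitted.
#' @return a \code{\linkS4class{PAVMatrix}}.
#' @examples
#' m <- matrix(c(1L, 0L, NA, 1L), 2, 2,
#'             dimnames = list(c("acc1", "acc2"), c("s1", "s2")))
#' pavMatrix(m)
#' @export
pavMatrix <- function(values, supportPresent = NULL, supportAbsent = NULL,
                      conflict = NULL) {
  if (is.character(values)) {
    v <- suppressWarnings(matrix(as.integer(values), nrow(values),
                                 dimnames = dimnames(values)))
    v[values == "?"] <- NA_integer_
    values <- v
  }
  storage.mode(values) <- "integer"
  z <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  new("PAVMatrix",
      values = values,
      supportPresent = if (is.null(supportPresent)) z else supportPresent,
      supportAbsent = if (is.null(supportAbsent)) z else supportAbsent,
      conflict = if (is.null(conflict)) z > 0L else conflict)
}

#' @rdname PAVMatrix-class
#' @param x a \code{PAVMatrix}
#' @export
pavValues <- function(x) x@values

#' @rdname PAVMatrix-class
#' @export
pavAccessions <- function(x) rownames(x@values)

#' @rdname PAVMatrix-class
#' @export
pavSites <- function(x) colnames(x@values)

#' @rdname PAVMatrix-class
#' @export
pavSupport <- function(x) list(present = x@supportPresent,
                               absent = x@supportAbsent)

#' Render a PAV matrix as characters ("1"/"0"/"?")
#' @param x a \code{PAVMatrix}
#' @export
pavCharacters <- function(x) {
  v <- x@values
  out <- matrix(as.character(v), nrow(v), dimnames = dimnames(v))
  out[is.na(v)] <- "?"
  out
}
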