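## Genome-wide TRIM identification and structural classification.
##
## The scanner is a deterministic surrogate for a homology search with manual
## curation: exact k-mer seeds anchor candidate windows, a local alignment
## against the consensus scores each window, and hits passing identity and
## coverage thresholds are merged into elements by a fixed gap rule.

nucSubMat <- function(match = 2L, mismatch = -1L) {
  b <- c(DNA_BASES4, "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- m[, "N"] <- 0L
  m
}

## Seed-and-extend search of one consensus component on one strand of one
## chromosome. Returns data.frame(start, end, identity, score) in subject
## coordinates.
scanComponent <- function(subject, component, minIdentity, minCoverage,
                          seedLength = 12L, pad = 30L) {
  compLen <- length(component)
  k <- min(seedLength, compLen)
  slen <- length(subject)
  if (slen < k) return(NULL)
  kmers <- Biostrings::DNAStringSet(component,
                                    start = seq_len(compLen - k + 1L),
                                    width = k)
  pd <- Biostrings::PDict(kmers)
  m <- Biostrings::matchPDict(pd, subject)
  starts <- IRanges::start(m)
  patPos <- rep.int(seq_along(kmers), lengths(starts))
  gPos <- unlist(starts, use.names = FALSE)
  if (!length(gPos)) return(NULL)
  diag <- gPos - patPos
  o <- order(diag, gPos)
  diag <- diag[o]; gPos <- gPos[o]; patPos <- patPos[o]
  ## cluster seeds: same copy means nearby diagonal
  cl <- cumsum(c(TRUE, diff(diag) > pad))
  ## within a diagonal band, far-apart genome positions are distinct copies
  for (cc in unique(cl)) {
    idx <- which(cl == cc)
    if (length(idx) > 1L) {
      oo <- order(gPos[idx])
      gaps <- diff(gPos[idx][oo])
      if (any(gaps > compLen)) {
        sub <- cumsum(c(0L, as.integer(gaps > compLen)))
        cl[idx[oo]] <- cl[idx[oo]] + sub / (max(sub) + 1)
      }
    }
  }
  hits <- lapply(split(seq_along(gPos), cl), function(idx) {
    ws <- max(1L, min(gPos[idx] - patPos[idx] + 1L) - pad)
    we <- min(slen, max(gPos[idx] - patPos[idx]) + compLen + pad)
    win <- Biostrings::subseq(subject, ws, we)
    aln <- Biostrings::pairwiseAlignment(
      component, win, type = "local",
      substitutionMatrix = nucSubMat(),
      gapOpening = 5, gapExtension = 1)
    idt <- Biostrings::pid(aln, type = "PID1") / 100
    pat <- Biostrings::pattern(aln)
    cov <- (IRanges::end(pat@range) - IRanges::start(pat@range) + 1L) / compLen
    if (idt < minIdentity || cov < minCoverage) return(NULL)
    sub <- Biostrings::subject(aln)
    data.frame(start = ws + IRanges::start(sub@range) - 1L,
               end = ws + IRanges::end(sub@range) - 1L,
               identity = idt,
               score = Biostrings::score(aln))
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits) || !nrow(hits)) return(NULL)
  ## de-duplicate overlapping hits of the same component: keep best score
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) for (j in (i + 1L):nrow(hits)) {
      if (!keep[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > 0.5 * min(hits$end[i] - hits$start[i] + 1L,
                         hits$end[j] - hits$start[j] + 1L))
        keep[j] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Scan a genome for TRIM component hits
#'
#' Reports every maximal local alignment of the LTR or internal consensus
#' with identity and consensus coverage above the model thresholds, on both
#' strands.
#'
#' @param genome a \code{DNAStringSet}.
#' @param model a \code{\linkS4class{TrimModel}}.
#' @param seedLength exact-seed length anchoring candidate windows.
#' @return a data.frame of hits: \code{chrom}, \code{start}, \code{end}
#'   (1-based), \code{strand}, \code{component} ("ltr"/"internal"),
#'   \code{identity}, \code{score}, sorted by coordinate.
#' @export
scanGenome <- function(genome, model, seedLength = 12L) {
  stopifnot(is(genome, "DNAStringSet"), is(model, "TrimModel"))
  if (!length(genome) || !sum(Biostrings::width(genome)))
    stop("genome must be non-empty")
  comps <- list(ltr = model@ltrConsensus, internal = model@internalConsensus)
  out <- list()
  for (ch in names(genome)) {
    chromSeq <- genome[[ch]]
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") chromSeq
                 else Biostrings::reverseComplement(chromSeq)
      for (compName in names(comps)) {
        h <- scanComponent(subject, comps[[compName]],
                           model@minIdentity, model@minCoverage, seedLength)
        if (is.null(h)) next
        if (strand == "-") {
          L <- length(chromSeq)
          tmp <- h$start
          h$start <- L - h$end + 1L
          h$end <- L - tmp + 1L
        }
        h$chrom <- ch
        h$strand <- strand
        h$component <- compName
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      component = character(), identity = numeric(),
                      score = numeric()))
  hits <- do.call(rbind, out)
  hits <- hits[, c("chrom", "start", "end", "strand", "component",
                   "identity", "score")]
  hits <- hits[order(match(hits$chrom, names(genome)), hits$start, hits$end), ]
  rownames(hits) <- NULL
  hits
}

#' Assemble component hits into annotated elements
#'
#' Adjacent same-strand hits within \code{gapTolerance} merge into one
#' element. Categories: >= 2 LTRs plus an internal segment is intact (with
#' the LTR count recorded — tandem multi-LTR arrangements keep all copies);
#' a lone LTR is a solo LTR; any other partial combination is truncated.
#' An internal gap longer than \code{nestedMinGap} that matched neither
#' consensus is recorded as a nested insertion.
#'
#' @param hits data.frame from \code{\link{scanGenome}}.
#' @param gapTolerance maximum bp gap joining hits into one element.
#' @param nestedMinGap minimum internal gap recorded as a nested insertion.
#' @return a \code{GRanges} with metadata columns \code{element_id},
#'   \code{category}, \code{ltr_count}, \code{identity},
#'   \code{ltr_intervals} ("start-end,..."), \code{nested} ("start-end,..."
#'   or NA), \code{tsd} (NA until \code{\link{detectTsd}}).
#' @export
assembleElements <- function(hits, gapTolerance = 2000L, nestedMinGap = 50L) {
  if (!nrow(hits)) return(GenomicRanges::GRanges())
  hits <- hits[order(hits$chrom, hits$start, hits$end), ]
  grp <- integer(nrow(hits))
  g <- 0L
  lastChrom <- ""; lastEnd <- -Inf; lastStrand <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$chrom[i] != lastChrom || hits$strand[i] != lastStrand ||
        hits$start[i] - lastEnd - 1L > gapTolerance) {
      g <- g + 1L
      lastEnd <- hits$end[i]
    } else {
      lastEnd <- max(lastEnd, hits$end[i])
    }
    grp[i] <- g
    lastChrom <- hits$chrom[i]
    lastStrand <- hits$strand[i]
  }
  rows <- lapply(split(seq_len(nrow(hits)), grp), function(idx) {
    h <- hits[idx, , drop = FALSE]
    nLtr <- sum(h$component == "ltr")
    hasInternal <- any(h$component == "internal")
    category <- if (nLtr >= 2L && hasInternal) "intact"
                else if (nLtr == 1L && !hasInternal) "solo_ltr"
                else "truncated"
    ltr <- h[h$component == "ltr", , drop = FALSE]
    gaps <- if (nrow(h) > 1L) {
      gs <- h$start[-1L] - h$end[-nrow(h)] - 1L
      big <- which(gs > nestedMinGap)
      if (length(big))
        paste(h$end[big] + 1L, h$start[big + 1L] - 1L, sep = "-",
              collapse = ",")
      else NA_character_
    } else NA_character_
    data.frame(chrom = h$chrom[1], start = min(h$start), end = max(h$end),
               strand = h$strand[1],
               category = category,
               ltr_count = nLtr,
               identity = mean(h$identity),
               ltr_intervals = if (nrow(ltr))
                 paste(ltr$start, ltr$end, sep = "-", collapse = ",")
               else NA_character_,
               nested = gaps,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), ]
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    element_id = sprintf("TRIM%03d", seq_len(nrow(df))),
    category = df$category,
    ltr_count = df$ltr_count,
    identity = df$identity,
    ltr_intervals = df$ltr_intervals,
    nested = df$nested,
    tsd = NA_character_)
}

#' Detect the target-site duplication of an element
#'
#' Compares the \code{tsdLength}-mers immediately flanking the element; the
#' TSD is reported only when the two flanking k-mers are identical. Elements
#' too close to a chromosome edge yield NA (not an error).
#'
#' @param genome a \code{DNAStringSet}.
#' @param chrom,start,end element location (1-based inclusive).
#' @param tsdLength expected TSD length (default 5).
#' @return the TSD sequence, or NA.
#' @export
detectTsd <- function(genome, chrom, start, end, tsdLength = 5L) {
  chromSeq <- genome[[chrom]]
  if (start - tsdLength < 1L || end + tsdLength > length(chromSeq))
    return(NA_character_)
  left <- as.character(Biostrings::subseq(chromSeq, start - tsdLength,
                                          start - 1L))
  right <- as.character(Biostrings::subseq(chromSeq, end + 1L,
                                           end + tsdLength))
  if (left == right) left else NA_character_
}

#' Annotate a genome end-to-end
#'
#' Convenience wrapper: scan, assemble, and attach TSDs.
#'
#' @param genome a \code{DNAStringSet}.
#' @param model a \code{\linkS4class{TrimModel}}.
#' @param gapTolerance,nestedMinGap see \code{\link{assembleElements}}.
#' @return annotated elements as a \code{GRanges}.
#' @examples
#' cfg <- trimSimConfig(seed = 5, chromosomeLengths = 20000L)
#' sim <- makeReferenceGenome(cfg, nIntact = 1, nSolo = 1, nTruncated = 0,
#'                            extraLtrCounts = integer(), nNested = 0)
#' ann <- annotateGenome(simGenome(sim), asTrimModel(simConsensus(sim)))
#' ann$category
#' @export
annotateGenome <- function(genome, model, gapTolerance = 2000L,
                           nestedMinGap = 50L) {
  hits <- scanGenome(genome, model)
  elements <- assembleElements(hits, gapTolerance, nestedMinGap)
  if (length(elements)) {
    elements$tsd <- vapply(seq_along(elements), function(i)
      detectTsd(genome,
                as.character(GenomicRanges::seqnames(elements)[i]),
                GenomicRanges::start(elements)[i],
                GenomicRanges::end(elements)[i],
                model@tsdLength),
      character(1))
  }
  elements
}

#' Per-chromosome element counts and densities
#'
#' Density is count per megabase, truncated to two decimals (the convention
#' of printed per-chromosome summary tables, where 27 elements on 143 Mb
#' appear as 0.18/Mb).
#'
#' @param elements a \code{GRanges} of elements, or a named integer vector of
#'   per-chromosome counts.
#' @param lengthsMb named numeric vector of chromosome lengths in Mb.
#' @return data.frame with \code{chrom}, \code{count}, \code{length_mb},
#'   \code{density}.
#' @examples
#' chromosomeDensity(c(chr10 = 27, chr6 = 12), c(chr10 = 143, chr6 = 161))
#' @export
chromosomeDensity <- function(elements, lengthsMb) {
  if (any(lengthsMb <= 0)) stop("chromosome lengths must be positive")
  counts <- if (is(elements, "GRanges")) {
    tab <- table(as.character(GenomicRanges::seqnames(elements)))
    out <- setNames(rep(0L, length(lengthsMb)), names(lengthsMb))
    out[names(tab)[names(tab) %in% names(out)]] <-
      as.integer(tab[names(tab) %in% names(out)])
    out
  } else {
    counts <- setNames(rep(0L, length(lengthsMb)), names(lengthsMb))
    counts[names(elements)] <- as.integer(elements)
    counts
  }
  data.frame(chrom = names(lengthsMb),
             count = as.integer(counts),
             length_mb = as.numeric(lengthsMb),
             density = floor(100 * counts / lengthsMb) / 100,
             row.names = NULL)
}

parseIntervalString <- function(x) {
  if (is.na(x) || !nzchar(x)) return(IRanges::IRanges())
  parts <- strsplit(strsplit(x, ",")[[1]], "-")
  IRanges::IRanges(as.integer(vapply(parts, `[`, "", 1L)),
                   as.integer(vapply(parts, `[`, "", 2L)))
}
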