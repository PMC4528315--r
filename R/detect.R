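## Non-reference insertion detection from paired-end reads, following the
## three-step junction-read procedure: (1) select reads containing an LTR
## terminus plus flanking genomic sequence, (2) map the flank to a unique
## reference locus, (3) cluster junction loci into insertion calls and
## compare against the reference annotation.

## terminal probes of the LTR used to anchor junction reads
ltrTerminalProbes <- function(ltr, minLtrMatch) {
  L <- length(ltr)
  list(start = Biostrings::subseq(ltr, 1L, minLtrMatch),
       end = Biostrings::subseq(ltr, L - minLtrMatch + 1L, L))
}

#' Select junction reads spanning an LTR terminus
#'
#' A read qualifies iff a terminal segment of the LTR (either end, either
#' read orientation) matches with at most \code{maxMismatch} mismatches over
#' at least \code{minLtrMatch} bases, and the remaining at least
#' \code{minFlank} bases are non-LTR. Reads matching only the LTR interior,
#' or whose flank itself contains an LTR terminal k-mer (e.g. reads from
#' tandem LTR-LTR junctions), are excluded: they carry no positional
#' information.
#'
#' @param reads a named \code{DNAStringSet}.
#' @param ltr the LTR consensus (\code{DNAString} or character).
#' @param minLtrMatch minimum LTR-terminal match length (default 20).
#' @param minFlank minimum flank length (default 20).
#' @param maxMismatch mismatches tolerated in the LTR part (default 1).
#' @return data.frame of junction reads: \code{read_id}, \code{orientation}
#'   ("fwd"/"rev" relative to the stored read), \code{ltr_end}
#'   ("ltr_start"/"ltr_end"), \code{ltr_match_length},
#'   \code{flank_side} ("left" = flank 5' of the element, "right" = 3'),
#'   \code{flank_sequence}.
#' @export
selectJunctionReads <- function(reads, ltr, minLtrMatch = 20L,
                                minFlank = 20L, maxMismatch = 1L) {
  stopifnot(is(reads, "DNAStringSet"))
  if (!length(reads)) stop("reads must be non-empty")
  ltr <- as(ltr, "DNAString")
  L <- length(ltr)
  probes <- ltrTerminalProbes(ltr, minLtrMatch)
  out <- list()
  orientations <- list(fwd = reads,
                       rev = Biostrings::reverseComplement(reads))
  for (ori in names(orientations)) {
    rs <- orientations[[ori]]
    ## ---- flank | LTR-start : read suffix matches an LTR prefix ----
    cand <- which(Biostrings::vcountPattern(probes$start, rs,
                                            max.mismatch = maxMismatch) > 0L)
    for (i in cand) {
      read <- rs[[i]]
      w <- length(read)
      m <- Biostrings::matchPattern(probes$start, read,
                                    max.mismatch = maxMismatch)
      for (p in sort(IRanges::start(m))) {
        ltrLen <- w - p + 1L
        if (p - 1L < minFlank || ltrLen < minLtrMatch || ltrLen > L) next
        ltrPart <- Biostrings::subseq(read, p, w)
        if (Biostrings::neditAt(ltrPart, ltr, at = 1L) > maxMismatch) next
        flank <- Biostrings::subseq(read, 1L, p - 1L)
        if (Biostrings::countPattern(probes$start, flank,
                                     max.mismatch = maxMismatch) +
            Biostrings::countPattern(probes$end, flank,
                                     max.mismatch = maxMismatch) > 0L) next
        out[[length(out) + 1L]] <- data.frame(
          read_id = names(rs)[i], orientation = ori,
          ltr_end = "ltr_start", ltr_match_length = ltrLen,
          flank_side = "left", flank_sequence = as.character(flank),
          stringsAsFactors = FALSE)
        break
      }
    }
    ## ---- LTR-end | flank : read prefix matches an LTR suffix ----
    cand <- which(Biostrings::vcountPattern(probes$end, rs,
                                            max.mismatch = maxMismatch) > 0L)
    for (i in cand) {
      read <- rs[[i]]
      w <- length(read)
      m <- Biostrings::matchPattern(probes$end, read,
                                    max.mismatch = maxMismatch)
      for (e in sort(IRanges::end(m), decreasing = TRUE)) {
        ltrLen <- e
        if (w - e < minFlank || ltrLen < minLtrMatch || ltrLen > L) next
        ltrPart <- Biostrings::subseq(read, 1L, e)
        if (Biostrings::neditAt(ltrPart, ltr,
                                at = L - ltrLen + 1L) > maxMismatch) next
        flank <- Biostrings::subseq(read, e + 1L, w)
        if (Biostrings::countPattern(probes$start, flank,
                                     max.mismatch = maxMismatch) +
            Biostrings::countPattern(probes$end, flank,
                                     max.mismatch = maxMismatch) > 0L) next
        out[[length(out) + 1L]] <- data.frame(
          read_id = names(rs)[i], orientation = ori,
          ltr_end = "ltr_end", ltr_match_length = ltrLen,
          flank_side = "right", flank_sequence = as.character(flank),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(), orientation = character(),
                      ltr_end = character(), ltr_match_length = integer(),
                      flank_side = character(), flank_sequence = character()))
  do.call(rbind, out)
}

#' Map a flank sequence to a unique reference locus
#'
#' Exhaustive search of both strands of every chromosome. Exactly one
#' qualifying locus is a unique mapping; two or more is ambiguous (the read
#' is discarded downstream); zero is unmapped.
#'
#' @param flank the flank sequence (character or \code{DNAString}).
#' @param reference a \code{DNAStringSet}.
#' @param maxMismatch mismatches tolerated (default 1).
#' @return list with \code{status} ("unique"/"ambiguous"/"unmapped") and,
#'   when unique, \code{chrom}, \code{start}, \code{end} (1-based),
#'   \code{strand}.
#' @export
mapFlankUnique <- function(flank, reference, maxMismatch = 1L) {
  flank <- as(flank, "DNAString")
  hits <- list()
  for (ch in names(reference)) {
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") flank
               else Biostrings::reverseComplement(flank)
      m <- Biostrings::matchPattern(probe, reference[[ch]],
                                    max.mismatch = maxMismatch)
      if (length(m))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = IRanges::start(m), end = IRanges::end(m),
          strand = strand, stringsAsFactors = FALSE)
      if (sum(vapply(hits, nrow, integer(1))) > 1L)
        return(list(status = "ambiguous"))
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(list(status = "unmapped"))
  list(status = "unique", chrom = hits$chrom[1L], start = hits$start[1L],
       end = hits$end[1L], strand = hits$strand[1L])
}

#' Map all junction reads, keeping uniquely placed ones
#'
#' @param junctionReads data.frame from \code{\link{selectJunctionReads}}.
#' @param reference a \code{DNAStringSet}.
#' @param maxMismatch passed to \code{\link{mapFlankUnique}}.
#' @return the uniquely mapped subset with \code{chrom}, \code{start},
#'   \code{end}, \code{strand} columns added.
#' @export
mapJunctionReads <- function(junctionReads, reference, maxMismatch = 1L) {
  if (!nrow(junctionReads))
    return(cbind(junctionReads,
                 data.frame(chrom = character(), start = integer(),
                            end = integer(), strand = character())))
  mapped <- lapply(junctionReads$flank_sequence, mapFlankUnique,
                   reference = reference, maxMismatch = maxMismatch)
  ok <- vapply(mapped, function(m) m$status == "unique", logical(1))
  res <- junctionReads[ok, , drop = FALSE]
  if (nrow(res)) {
    res$chrom <- vapply(mapped[ok], `[[`, "", "chrom")
    res$start <- vapply(mapped[ok], function(m) as.integer(m$start), 1L)
    res$end <- vapply(mapped[ok], function(m) as.integer(m$end), 1L)
    res$strand <- vapply(mapped[ok], `[[`, "", "strand")
  }
  res
}

## cluster sorted integer positions: new cluster when gap > window
clusterPositions <- function(pos, window) {
  o <- order(pos)
  cl <- cumsum(c(TRUE, diff(pos[o]) > window))
  ids <- integer(length(pos))
  ids[o] <- cl
  ids
}

#' Cluster mapped junction reads into insertion calls
#'
#' Junction loci are expressed as 0-based inter-base offsets in reference
#' coordinates: the left junction is the offset where reference sequence
#' gives way to the element, the right junction where it resumes. Loci
#' within \code{clusterWindow} merge; left and right clusters pair into one
#' site when the offset between them (the TSD length) lies in
#' \code{[0, maxTsd]}. The TSD is the reference sequence between the right-
#' and left-junction offsets. Calls overlapping an annotated reference
#' element are labelled \code{reference}, all others \code{non_reference}.
#'
#' @param mappedReads data.frame from \code{\link{mapJunctionReads}}.
#' @param reference a \code{DNAStringSet} (for TSD extraction).
#' @param referenceElements optional annotated \code{GRanges} of the
#'   reference genome.
#' @param clusterWindow cluster width in bp (default 10).
#' @param maxTsd maximum TSD length considered (default 10).
#' @return data.frame of calls: \code{chrom}, \code{pos} (0-based insertion
#'   offset), \code{orientation}, \code{tsd}, \code{support_left},
#'   \code{support_right}, \code{status}.
#' @export
callInsertions <- function(mappedReads, reference, referenceElements = NULL,
                           clusterWindow = 10L, maxTsd = 10L) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      orientation = character(), tsd = character(),
                      support_left = integer(), support_right = integer(),
                      status = character())
  if (!nrow(mappedReads)) return(empty)
  m <- mappedReads
  ## junction side in reference coordinates
  refLeft <- (m$flank_side == "left" & m$strand == "+") |
             (m$flank_side == "right" & m$strand == "-")
  m$junction <- ifelse(refLeft, "L", "R")
  m$offset <- ifelse(refLeft, m$end, m$start - 1L)
  m$elem_orient <- ifelse(m$strand == "+", "+", "-")

  calls <- list()
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, , drop = FALSE]
    clusters <- list()
    for (side in c("L", "R")) {
      s <- sub[sub$junction == side, , drop = FALSE]
      if (!nrow(s)) next
      ids <- clusterPositions(s$offset, clusterWindow)
      for (cc in unique(ids)) {
        grp <- s[ids == cc, , drop = FALSE]
        clusters[[length(clusters) + 1L]] <- list(
          side = side,
          pos = as.integer(round(stats::median(grp$offset))),
          n = nrow(grp),
          orient = names(sort(table(grp$elem_orient), decreasing = TRUE))[1L])
      }
    }
    left <- Filter(function(x) x$side == "L", clusters)
    right <- Filter(function(x) x$side == "R", clusters)
    usedR <- logical(length(right))
    for (lc in left) {
      dists <- vapply(right, function(rc) lc$pos - rc$pos, numeric(1))
      okR <- which(!usedR & dists >= 0 & dists <= maxTsd)
      if (length(okR)) {
        j <- okR[which.min(dists[okR])]
        rc <- right[[j]]
        usedR[j] <- TRUE
        tsdLen <- lc$pos - rc$pos
        tsd <- if (tsdLen > 0L)
          as.character(Biostrings::subseq(reference[[ch]], rc$pos + 1L,
                                          lc$pos))
        else ""
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch, pos = lc$pos, orientation = lc$orient, tsd = tsd,
          support_left = lc$n, support_right = rc$n,
          stringsAsFactors = FALSE)
      } else {
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch, pos = lc$pos, orientation = lc$orient,
          tsd = NA_character_, support_left = lc$n, support_right = 0L,
          stringsAsFactors = FALSE)
      }
    }
    for (j in which(!usedR)) {
      rc <- right[[j]]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, pos = rc$pos, orientation = rc$orient,
        tsd = NA_character_, support_left = 0L, support_right = rc$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, calls)
  out <- out[order(match(out$chrom, names(reference)), out$pos), ]
  rownames(out) <- NULL
  out$status <- "non_reference"
  if (!is.null(referenceElements) && length(referenceElements)) {
    sites <- GenomicRanges::GRanges(
      out$chrom, IRanges::IRanges(pmax(out$pos - 20L, 1L), out$pos + 20L))
    ov <- GenomicRanges::countOverlaps(sites, referenceElements) > 0L
    out$status[ov] <- "reference"
  }
  out
}

#' Detect insertions from reads in one call
#'
#' Chains \code{\link{selectJunctionReads}}, \code{\link{mapJunctionReads}},
#' and \code{\link{callInsertions}}.
#'
#' @param reads a named \code{DNAStringSet} (pool both mates).
#' @param ltr the LTR consensus.
#' @param reference a \code{DNAStringSet}.
#' @param referenceElements optional annotated reference \code{GRanges}.
#' @param minLtrMatch,minFlank,maxMismatch,clusterWindow,maxTsd see the
#'   stage functions.
#' @return the insertion-call data.frame.
#' @export
detectInsertions <- function(reads, ltr, reference, referenceElements = NULL,
                             minLtrMatch = 20L, minFlank = 20L,
                             maxMismatch = 1L, clusterWindow = 10L,
                             maxTsd = 10L) {
  jr <- selectJunctionReads(reads, ltr, minLtrMatch, minFlank, maxMismatch)
  mapped <- mapJunctionReads(jr, reference, maxMismatch)
  callInsertions(mapped, reference, referenceElements, clusterWindow, maxTsd)
}

#' Summarize insertion sharing across lines
#'
#' Classifies each distinct site by carrier count: line-specific (1),
#' present in exactly two lines (2), or present in multiple (>= 3) lines —
#' the only partition of those labels whose classes are disjoint and sum to
#' the total. Percentages are rounded to the nearest percent.
#'
#' @param callsByLine named list: line -> data.frame of calls (or character
#'   vector of "chrom:pos" site keys).
#' @param clusterWindow sites within this many bp across lines are treated
#'   as one site.
#' @return data.frame with rows line_specific / two_lines / multi_line and
#'   columns \code{count}, \code{percent}; total sites in
#'   \code{attr(, "total")}.
#' @examples
#' x <- list(a = "chr1:100", b = c("chr1:100", "chr2:50"), c = "chr1:100")
#' sharingSummary(x)
#' @export
sharingSummary <- function(callsByLine, clusterWindow = 10L) {
  if (!length(callsByLine)) stop("callsByLine must be non-empty")
  keys <- lapply(callsByLine, function(x) {
    if (is.data.frame(x)) paste0(x$chrom, ":", x$pos) else as.character(x)
  })
  df <- data.frame(
    line = rep(names(keys), lengths(keys)),
    key = unlist(keys, use.names = FALSE), stringsAsFactors = FALSE)
  parts <- strsplit(df$key, ":", fixed = TRUE)
  df$chrom <- vapply(parts, `[`, "", 1L)
  df$pos <- as.integer(vapply(parts, `[`, "", 2L))
  ## unify site identities across lines
  df$site <- NA_integer_
  nextId <- 0L
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    ids <- clusterPositions(df$pos[idx], clusterWindow)
    df$site[idx] <- ids + nextId
    nextId <- nextId + max(ids)
  }
  carriers <- vapply(split(df$line, df$site),
                     function(x) length(unique(x)), integer(1))
  total <- length(carriers)
  counts <- c(line_specific = sum(carriers == 1L),
              two_lines = sum(carriers == 2L),
              multi_line = sum(carriers >= 3L))
  out <- data.frame(class = names(counts),
                    count = as.integer(counts),
                    percent = roundHalfUp(100 * counts / total),
                    row.names = NULL)
  attr(out, "total") <- total
  out
}
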