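## Insertion-site sequence logos and conserved-motif discovery.

#' Position frequency and information content of TSD + flank records
#'
#' Computes per-position base frequencies over A/C/G/T and the information
#' content 2 - H (Shannon entropy, base 2) at each position. Raw
#' frequencies, no pseudocounts, and no small-sample correction by default —
#' the plain sequence-logo definition.
#'
#' @param records character vector (or \code{DNAStringSet}) of equal-length
#'   TSD-plus-flank sequences.
#' @param smallSampleCorrection subtract the Miller-Madow correction
#'   (s-1)/(2 ln(2) n) from the information content (off by default).
#' @return a list of class \code{trimLogo}: \code{frequencies} (4 x L
#'   matrix), \code{information} (length-L vector of bits in [0, 2]),
#'   \code{n} (record count).
#' @examples
#' tsdLogo(c("ACGTA", "ACGTA", "ACGTT"))
#' @export
tsdLogo <- function(records, smallSampleCorrection = FALSE) {
  records <- as.character(records)
  if (!length(records)) stop("no TSD records supplied")
  L <- unique(nchar(records))
  if (length(L) != 1L) stop("all records must have the same length")
  mat <- do.call(rbind, strsplit(toupper(records), ""))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = DNA_BASES4))
    as.numeric(tab) / sum(tab)
  }, numeric(4L))
  rownames(freq) <- DNA_BASES4
  colnames(freq) <- seq_len(L)
  ent <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info <- 2 - ent
  if (smallSampleCorrection)
    info <- pmax(0, info - 3 / (2 * log(2) * length(records)))
  structure(list(frequencies = freq, information = unname(info),
                 n = length(records)),
            class = "trimLogo")
}

#' @export
print.trimLogo <- function(x, ...) {
  cat("TSD/flank logo over", x$n, "records,", ncol(x$frequencies),
      "positions; information (bits):\n")
  print(round(x$information, 3))
  invisible(x)
}

#' Find substrings exactly shared by two sets of LTR sequences
#'
#' Returns all maximal substrings of length >= \code{minLength} present
#' verbatim in every sequence of both sets — e.g. the conserved LTR motif
#' shared between a TRIM family and its candidate autonomous partner.
#'
#' @param setA,setB character vectors (or \code{DNAStringSet}s) of sequences.
#' @param minLength minimum motif length (default 12).
#' @return character vector of maximal shared motifs (possibly empty).
#' @examples
#' findConservedMotif("AAGGTTCCAAGGTT", "CCAAGGTTCC", minLength = 6)
#' @export
findConservedMotif <- function(setA, setB, minLength = 12L) {
  seqs <- c(as.character(setA), as.character(setB))
  if (length(seqs) < 2L) stop("both sets must be non-empty")
  ref <- seqs[[which.min(nchar(seqs))]]
  others <- seqs[-which.min(nchar(seqs))]
  n <- nchar(ref)
  if (n < minLength) return(character())
  sharedAll <- function(motif)
    all(vapply(others, function(s) grepl(motif, s, fixed = TRUE), logical(1)))
  cand <- character()
  for (i in seq_len(n - minLength + 1L)) {
    if (!sharedAll(substr(ref, i, i + minLength - 1L))) next
    lo <- minLength
    hi <- n - i + 1L
    while (lo < hi) {  # largest L with shared substring (monotone in L)
      mid <- lo + (hi - lo + 1L) %/% 2L
      if (sharedAll(substr(ref, i, i + mid - 1L))) lo <- mid else hi <- mid - 1L
    }
    cand <- c(cand, substr(ref, i, i + lo - 1L))
  }
  cand <- unique(cand)
  if (!length(cand)) return(character())
  maximal <- vapply(seq_along(cand), function(i)
    !any(vapply(seq_along(cand)[-i], function(j)
      grepl(cand[i], cand[j], fixed = TRUE) &&
        nchar(cand[j]) >= nchar(cand[i]) && cand[j] != cand[i],
      logical(1))), logical(1))
  sort(cand[maximal])
}

#' Locate PBS and PPT motifs in an intact element
#'
#' The primer-binding site is the best match (within \code{maxMismatch}) to
#' the reverse complement of a primer tRNA 3' terminus, searched in a window
#' immediately downstream of the 5' LTR; the polypurine tract is a purine run
#' of at least \code{minPptPurines} bases immediately upstream of the
#' 3'-most LTR. Either motif may be absent.
#'
#' @param genome a \code{DNAStringSet}.
#' @param element a length-1 \code{GRanges} from \code{\link{annotateGenome}}
#'   with \code{category == "intact"} and an \code{ltr_intervals} column.
#' @param primerLibrary character vector of primer tRNA sequences.
#' @param minPptPurines minimum purine-run length for a PPT call.
#' @param window search-window width in bp.
#' @param maxMismatch mismatches tolerated in the PBS match.
#' @return list with \code{pbs} and \code{ppt}, each either NULL or a list
#'   \code{start}, \code{end} (element-forward 1-based coordinates),
#'   \code{seq}.
#' @export
detectPbsPpt <- function(genome, element,
                         primerLibrary = PRIMER_TRNA_IMET,
                         minPptPurines = 10L, window = 30L,
                         maxMismatch = 2L) {
  stopifnot(is(element, "GRanges"), length(element) == 1L)
  if (element$category != "intact")
    stop("PBS/PPT detection requires an intact element")
  chrom <- as.character(GenomicRanges::seqnames(element))
  s <- GenomicRanges::start(element)
  e <- GenomicRanges::end(element)
  elemSeq <- Biostrings::subseq(genome[[chrom]], s, e)
  ltrAbs <- parseIntervalString(element$ltr_intervals)
  ## element-forward coordinates of the LTR copies
  rel <- IRanges::IRanges(IRanges::start(ltrAbs) - s + 1L,
                          IRanges::end(ltrAbs) - s + 1L)
  if (as.character(GenomicRanges::strand(element)) == "-") {
    elemSeq <- Biostrings::reverseComplement(elemSeq)
    len <- e - s + 1L
    rel <- sortByStart(IRanges::IRanges(len - IRanges::end(rel) + 1L,
                                        len - IRanges::start(rel) + 1L))
  }
  ltr5End <- IRanges::end(rel)[1L]
  ltr3Start <- IRanges::start(rel)[length(rel)]

  pbs <- NULL
  winEnd <- min(ltr5End + window, length(elemSeq))
  if (winEnd > ltr5End) {
    win <- Biostrings::subseq(elemSeq, ltr5End + 1L, winEnd)
    best <- NULL
    for (primer in primerLibrary) {
      probe <- Biostrings::reverseComplement(Biostrings::DNAString(
        substr(primer, nchar(primer) - PBS_MOTIF_LENGTH + 1L, nchar(primer))))
      m <- Biostrings::matchPattern(probe, win, max.mismatch = maxMismatch)
      if (length(m)) {
        mm <- Biostrings::neditAt(probe, win, at = IRanges::start(m)[1L])
        if (is.null(best) || mm < best$mm)
          best <- list(start = ltr5End + IRanges::start(m)[1L],
                       end = ltr5End + IRanges::end(m)[1L], mm = mm)
      }
    }
    if (!is.null(best))
      pbs <- list(start = best$start, end = best$end,
                  seq = as.character(Biostrings::subseq(elemSeq, best$start,
                                                        best$end)))
  }

  ppt <- NULL
  winStart <- max(ltr3Start - window, 1L)
  if (winStart < ltr3Start) {
    win <- as.character(Biostrings::subseq(elemSeq, winStart, ltr3Start - 1L))
    m <- gregexpr(paste0("[AG]{", minPptPurines, ",}"), win)[[1L]]
    if (m[1L] != -1L) {
      lens <- attr(m, "match.length")
      i <- which.max(lens)   # longest purine run wins
      ppt <- list(start = winStart + m[i] - 1L,
                  end = winStart + m[i] + lens[i] - 2L,
                  seq = substr(win, m[i], m[i] + lens[i] - 1L))
    }
  }
  list(pbs = pbs, ppt = ppt)
}
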