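## Insertion dating from LTR-pair divergence under the Kimura two-parameter
## model: at integration the two LTRs are identical, so their divergence K
## clocks the element's age as T = K / (2 r).

#' Globally align an LTR pair
#'
#' Needleman-Wunsch with affine gaps (match +2, mismatch -1, gap open -5,
#' gap extend -1). The scoring constants are configuration, not contract.
#'
#' @param ltr5,ltr3 the two LTR sequences (character or \code{DNAString}).
#' @return list with \code{aligned5} and \code{aligned3}, equal-length
#'   gapped character strings.
#' @export
alignLtrPair <- function(ltr5, ltr3) {
  ltr5 <- as(ltr5, "DNAString")
  ltr3 <- as(ltr3, "DNAString")
  if (!length(ltr5) || !length(ltr3))
    stop("both LTR sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    ltr5, ltr3, type = "global",
    substitutionMatrix = nucSubMat(),
    gapOpening = 5, gapExtension = 1)
  list(aligned5 = as.character(Biostrings::alignedPattern(aln)),
       aligned3 = as.character(Biostrings::alignedSubject(aln)))
}

TRANSITION_PAIRS <- c("AG", "GA", "CT", "TC")

#' Kimura two-parameter divergence of an aligned pair
#'
#' Over gap-free columns, P is the transition proportion, Q the transversion
#' proportion, and K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). Gapped columns
#' are excluded pairwise by default; \code{completeDeletion} additionally
#' drops columns containing any ambiguity code.
#'
#' @param x,y equal-length aligned sequences (gaps as "-"), or \code{x} a
#'   list with \code{aligned5}/\code{aligned3} as returned by
#'   \code{\link{alignLtrPair}}.
#' @param completeDeletion kept for interface symmetry with multi-sequence
#'   distance tools; for a single pair, pairwise and complete deletion drop
#'   the same columns (those with a gap or ambiguity in either sequence).
#' @return list with \code{sites} (compared columns), \code{P}, \code{Q},
#'   \code{K}.
#' @section Saturation: when 1 - 2P - Q <= 0 or 1 - 2Q <= 0 the distance is
#'   undefined; a condition of class \code{trimSaturationError} is signalled
#'   and the element should be excluded (and logged) by the caller.
#' @examples
#' kimura2p("ACGTACGTAC", "ACGTACGTAC")$K  # 0
#' @export
kimura2p <- function(x, y = NULL, completeDeletion = FALSE) {
  if (is.null(y)) {
    y <- x$aligned3
    x <- x$aligned5
  }
  a <- strsplit(toupper(as.character(x)), "")[[1]]
  b <- strsplit(toupper(as.character(y)), "")[[1]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  ## for a single pair, pairwise and complete (listwise) deletion coincide:
  ## a column is compared iff both sequences carry an unambiguous base
  ok <- a != "-" & b != "-" & a %in% DNA_BASES4 & b %in% DNA_BASES4
  n <- sum(ok)
  if (n < 1L) stop("no ungapped columns to compare")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  pairs <- paste0(a[diff], b[diff])
  nTs <- sum(pairs %in% TRANSITION_PAIRS)
  nTv <- sum(diff) - nTs
  P <- nTs / n
  Q <- nTv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    cond <- structure(
      class = c("trimSaturationError", "error", "condition"),
      list(message = sprintf(
             "saturated LTR pair (P = %.3f, Q = %.3f): K2P distance undefined",
             P, Q),
           call = sys.call(-1L), P = P, Q = Q))
    stop(cond)
  }
  K <- -0.5 * log(w1) - 0.25 * log(w2)
  list(sites = n, P = P, Q = Q, K = K)
}

#' Convert divergence to insertion time
#'
#' T = K / (2 r), with r the per-site per-year substitution rate
#' (default 1.3e-8).
#'
#' @param K substitutions per site (>= 0).
#' @param r substitution rate per site per year (> 0).
#' @return insertion time in years.
#' @examples
#' insertionTime(0.026)  # 1e6 years
#' @export
insertionTime <- function(K, r = 1.3e-8) {
  if (any(r <= 0)) stop("substitution rate r must be positive")
  if (any(K < 0)) stop("K must be non-negative")
  K / (2 * r)
}

#' Date all intact elements of an annotated genome
#'
#' For each intact element, extracts the 5'-most and 3'-most LTR copies
#' (strand-aware), aligns them, estimates the K2P divergence, and converts it
#' to an insertion time. Saturated or unalignable pairs are excluded and
#' reported in the \code{excluded} attribute.
#'
#' @param genome a \code{DNAStringSet}.
#' @param elements annotated \code{GRanges} from \code{\link{annotateGenome}}.
#' @param r substitution rate per site per year.
#' @param completeDeletion passed to \code{\link{kimura2p}}.
#' @return data.frame with one row per dated element: \code{element_id},
#'   \code{aligned_length}, \code{P}, \code{Q}, \code{K}, \code{T},
#'   \code{r}; excluded element ids in \code{attr(, "excluded")}.
#' @export
dateElements <- function(genome, elements, r = 1.3e-8,
                         completeDeletion = FALSE) {
  intact <- elements[elements$category == "intact" & elements$ltr_count >= 2L]
  rows <- list()
  excluded <- character()
  for (i in seq_along(intact)) {
    el <- intact[i]
    chrom <- as.character(GenomicRanges::seqnames(el))
    iv <- parseIntervalString(el$ltr_intervals)
    iv <- sortByStart(iv)
    first <- Biostrings::subseq(genome[[chrom]], IRanges::start(iv)[1L],
                                IRanges::end(iv)[1L])
    lastIdx <- length(iv)
    last <- Biostrings::subseq(genome[[chrom]], IRanges::start(iv)[lastIdx],
                               IRanges::end(iv)[lastIdx])
    if (as.character(GenomicRanges::strand(el)) == "-") {
      tmp <- Biostrings::reverseComplement(last)
      last <- Biostrings::reverseComplement(first)
      first <- tmp
    }
    est <- tryCatch({
      aln <- alignLtrPair(first, last)
      k2p <- kimura2p(aln, completeDeletion = completeDeletion)
      data.frame(element_id = el$element_id,
                 aligned_length = k2p$sites,
                 P = k2p$P, Q = k2p$Q, K = k2p$K,
                 T = insertionTime(k2p$K, r), r = r,
                 stringsAsFactors = FALSE)
    }, trimSaturationError = function(cond) {
      message("excluding ", el$element_id, ": ", conditionMessage(cond))
      NULL
    })
    if (is.null(est)) excluded <- c(excluded, el$element_id)
    else rows[[length(rows) + 1L]] <- est
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(element_id = character(), aligned_length = integer(),
                         P = numeric(), Q = numeric(), K = numeric(),
                         T = numeric(), r = numeric())
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Histogram of insertion ages
#'
#' Left-closed, right-open bins of \code{binWidthYears}; per-bin fractions
#' are count/total rounded to the nearest percent.
#'
#' @param ageYears numeric vector of insertion times in years (or a
#'   data.frame from \code{\link{dateElements}}, whose \code{T} column is
#'   used).
#' @param binWidthYears bin width (default 1 Myr).
#' @return data.frame with \code{bin_start_myr}, \code{bin_end_myr},
#'   \code{count}, \code{percent}.
#' @examples
#' ageHistogram(c(rep(5e5, 32), rep(2.5e6, 48)))$percent[1]  # 40
#' @export
ageHistogram <- function(ageYears, binWidthYears = 1e6) {
  if (is.data.frame(ageYears)) ageYears <- ageYears$T
  if (!length(ageYears)) stop("no age estimates supplied")
  bin <- floor(ageYears / binWidthYears)
  nBins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nBins)
  data.frame(bin_start_myr = (seq_len(nBins) - 1L) * binWidthYears / 1e6,
             bin_end_myr = seq_len(nBins) * binWidthYears / 1e6,
             count = counts,
             percent = roundHalfUp(100 * counts / length(ageYears)))
}
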