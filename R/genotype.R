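## Presence/absence genotyping of known insertion sites from raw reads,
## using the 150-bp flanking sequences of each site to build presence- and
## absence-allele junction signatures.

#' Extract flanking sequences and allele signatures for a site
#'
#' For a non-reference site (a 0-based insertion offset in reference
#' coordinates) the presence-allele junctions are flank end + LTR terminus
#' (the 3' junction additionally crosses the duplicated TSD) and the
#' absence-allele junction is the unbroken reference across the offset. For
#' a reference-carried site (pass the annotated \code{element}) the presence
#' signatures use the element's actual termini and the absence allele is the
#' precise-excision sequence (flanks joined, one TSD copy retained).
#'
#' @param reference a \code{DNAStringSet}.
#' @param chrom chromosome name (ignored when \code{element} is given).
#' @param pos 0-based insertion offset (ignored when \code{element} is given).
#' @param ltr the LTR consensus (character or \code{DNAString}).
#' @param flank flank length in bp (default 150).
#' @param tsdLength TSD length in bp (default 5).
#' @param element optional length-1 annotated \code{GRanges} for a
#'   reference-carried site.
#' @param siteId identifier for the site.
#' @return an object of class \code{siteFlanks}: \code{site_id},
#'   \code{chrom}, \code{pos}, \code{left_flank}, \code{right_flank},
#'   \code{junction_present_left}, \code{junction_present_right},
#'   \code{junction_absent} (each junction a list of \code{left}/\code{right}
#'   half sequences joined at the breakpoint).
#' @export
extractSiteFlanks <- function(reference, chrom, pos, ltr, flank = 150L,
                              tsdLength = 5L, element = NULL,
                              siteId = NULL) {
  ltr <- as.character(ltr)
  if (!is.null(element)) {
    stopifnot(is(element, "GRanges"), length(element) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(element))
    s <- GenomicRanges::start(element)
    e <- GenomicRanges::end(element)
    chromSeq <- reference[[chrom]]
    pos <- s - 1L
    lf0 <- max(1L, s - flank)
    rf1 <- min(length(chromSeq), e + flank)
    if (lf0 > s - flank || rf1 < e + flank)
      warning("site ", siteId %||% pos,
              ": flank shortened at chromosome edge")
    leftFlank <- as.character(Biostrings::subseq(chromSeq, lf0, s - 1L))
    ## absence allele = precise excision: one TSD copy retained
    rightAbsent <- as.character(Biostrings::subseq(
      chromSeq, min(e + tsdLength + 1L, length(chromSeq)),
      min(e + tsdLength + flank, length(chromSeq))))
    rightPresent <- as.character(Biostrings::subseq(
      chromSeq, e + 1L, rf1))
    elemSeq <- as.character(Biostrings::subseq(chromSeq, s, e))
    presentLeftRight <- elemSeq
    presentRightLeft <- elemSeq
    rightFlank <- rightAbsent
  } else {
    chromSeq <- reference[[chrom]]
    pos <- as.integer(pos)
    lf0 <- max(1L, pos - flank + 1L)
    rf1 <- min(length(chromSeq), pos + flank)
    if (pos - flank + 1L < 1L || pos + flank > length(chromSeq))
      warning("site ", siteId %||% pos,
              ": flank shortened at chromosome edge")
    leftFlank <- as.character(Biostrings::subseq(chromSeq, lf0, pos))
    rightFlank <- as.character(Biostrings::subseq(chromSeq, pos + 1L, rf1))
    tsd <- if (tsdLength > 0L)
      substr(leftFlank, nchar(leftFlank) - tsdLength + 1L, nchar(leftFlank))
    else ""
    presentLeftRight <- ltr                      # element begins with its LTR
    presentRightLeft <- ltr                      # and ends with one
    rightPresent <- paste0(tsd, rightFlank)      # duplicated TSD, then ref
    rightAbsent <- rightFlank
  }
  structure(list(
    site_id = siteId %||% paste0(chrom, ":", pos),
    chrom = chrom, pos = pos,
    left_flank = leftFlank,
    right_flank = rightFlank,
    junction_present_left = list(left = leftFlank, right = presentLeftRight),
    junction_present_right = list(left = presentRightLeft,
                                  right = rightPresent),
    junction_absent = list(left = leftFlank, right = rightAbsent)),
    class = "siteFlanks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Junction probe: `overlap` bases either side of the breakpoint.
junctionProbe <- function(junction, overlap) {
  l <- junction$left
  r <- junction$right
  paste0(substr(l, nchar(l) - overlap + 1L, nchar(l)),
         substr(r, 1L, overlap))
}

## Count reads containing the probe (either strand).
countSupport <- function(reads, probe, maxMismatch) {
  p <- Biostrings::DNAString(probe)
  fwd <- Biostrings::vcountPattern(p, reads, max.mismatch = maxMismatch)
  rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(p), reads,
                                   max.mismatch = maxMismatch)
  sum(fwd + rev > 0L)
}

#' Genotype one site from one accession's reads
#'
#' A read spanning a presence-allele junction by at least
#' \code{minJunctionOverlap} bases on both sides supports presence; a read
#' spanning the absence-allele junction likewise supports absence. The cell
#' is 1 when presence support reaches \code{minSupport} with zero absence
#' support, 0 in the converse case, and missing ("?") when no informative
#' reads exist — or when both alleles are supported, which is flagged as a
#' conflict rather than resolved by vote.
#'
#' @param reads a \code{DNAStringSet}.
#' @param flanks a \code{siteFlanks} object.
#' @param minJunctionOverlap bases required either side of the junction.
#' @param mismatchPer20 mismatches tolerated per 20 bp of probe (default 1;
#'   0 gives exact matching).
#' @param minSupport reads required to call an allele (default 1).
#' @return list: \code{value} (1L / 0L / NA), \code{supportPresent},
#'   \code{supportAbsent}, \code{conflict}.
#' @export
genotypeSite <- function(reads, flanks, minJunctionOverlap = 20L,
                         mismatchPer20 = 1L, minSupport = 1L) {
  stopifnot(inherits(flanks, "siteFlanks"))
  o <- minJunctionOverlap
  maxMis <- as.integer(mismatchPer20 * (2L * o) / 20L)
  supP <- countSupport(reads, junctionProbe(flanks$junction_present_left, o),
                       maxMis) +
          countSupport(reads, junctionProbe(flanks$junction_present_right, o),
                       maxMis)
  supA <- countSupport(reads, junctionProbe(flanks$junction_absent, o),
                       maxMis)
  conflict <- supP > 0L && supA > 0L
  value <- if (conflict) NA_integer_
           else if (supP >= minSupport && supA == 0L) 1L
           else if (supA >= minSupport && supP == 0L) 0L
           else NA_integer_
  list(value = value, supportPresent = supP, supportAbsent = supA,
       conflict = conflict)
}

#' Build the presence/absence matrix for an accession panel
#'
#' Cell-wise application of \code{\link{genotypeSite}} with deterministic
#' row (accession) and column (site) ordering.
#'
#' @param readSets named list: accession -> \code{DNAStringSet} (pool both
#'   mates).
#' @param siteFlanksList list of \code{siteFlanks} objects.
#' @param ... passed to \code{\link{genotypeSite}}.
#' @return a \code{\linkS4class{PAVMatrix}}.
#' @export
buildPavMatrix <- function(readSets, siteFlanksList,
                           minJunctionOverlap = 20L, mismatchPer20 = 1L,
                           minSupport = 1L) {
  if (!length(readSets) || !length(siteFlanksList))
    stop("need at least one accession and one site")
  o <- minJunctionOverlap
  maxMis <- as.integer(mismatchPer20 * (2L * o) / 20L)
  accs <- names(readSets)
  siteIds <- vapply(siteFlanksList, `[[`, "", "site_id")
  dims <- list(accs, siteIds)
  values <- matrix(NA_integer_, length(accs), length(siteIds),
                   dimnames = dims)
  supP <- supA <- matrix(0L, length(accs), length(siteIds), dimnames = dims)
  conf <- matrix(FALSE, length(accs), length(siteIds), dimnames = dims)

  ## batch full-length probes into one dictionary so each accession's reads
  ## are scanned once; edge-shortened probes fall back to per-site scans
  probes <- lapply(siteFlanksList, function(fl) c(
    P1 = junctionProbe(fl$junction_present_left, o),
    P2 = junctionProbe(fl$junction_present_right, o),
    A = junctionProbe(fl$junction_absent, o)))
  full <- vapply(probes, function(p) all(nchar(p) == 2L * o), logical(1))
  batch <- which(full)
  if (length(batch)) {
    patSeq <- Biostrings::DNAStringSet(unlist(probes[batch]))
    patSite <- rep(batch, each = 3L)
    patClass <- rep(c("P", "P", "A"), length(batch))
    allPat <- c(patSeq, Biostrings::reverseComplement(patSeq))
    names(allPat) <- NULL
    patSite <- c(patSite, patSite)
    patClass <- c(patClass, patClass)
    pd <- if (maxMis > 0L) Biostrings::PDict(allPat, max.mismatch = maxMis)
          else Biostrings::PDict(allPat)
    for (a in accs) {
      hits <- Biostrings::vwhichPDict(pd, readSets[[a]],
                                      max.mismatch = maxMis)
      if (sum(lengths(hits))) {
        df <- unique(data.frame(
          read = rep.int(seq_along(hits), lengths(hits)),
          site = patSite[unlist(hits, use.names = FALSE)],
          class = patClass[unlist(hits, use.names = FALSE)]))
        tab <- table(factor(df$site, levels = batch), df$class)
        if ("P" %in% colnames(tab))
          supP[a, batch] <- as.integer(tab[, "P"])
        if ("A" %in% colnames(tab))
          supA[a, batch] <- as.integer(tab[, "A"])
      }
    }
  }
  for (j in which(!full)) {
    for (a in accs) {
      g <- genotypeSite(readSets[[a]], siteFlanksList[[j]],
                        minJunctionOverlap = o, mismatchPer20 = mismatchPer20,
                        minSupport = minSupport)
      supP[a, j] <- g$supportPresent
      supA[a, j] <- g$supportAbsent
    }
  }
  conf[] <- supP > 0L & supA > 0L
  values[] <- ifelse(conf, NA_integer_,
                     ifelse(supP >= minSupport & supA == 0L, 1L,
                            ifelse(supA >= minSupport & supP == 0L, 0L,
                                   NA_integer_)))
  new("PAVMatrix", values = values, supportPresent = supP,
      supportAbsent = supA, conflict = conf)
}

#' Fraction of callable (non-missing) cells
#'
#' @param pav a \code{\linkS4class{PAVMatrix}} (or integer matrix with NA
#'   for missing).
#' @param groups optional named character vector accession -> group for
#'   per-group rates.
#' @return data.frame with \code{group} ("overall" first), \code{called},
#'   \code{total}, \code{rate_percent} (nearest percent).
#' @examples
#' m <- matrix(c(1L, NA, 0L, 1L), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' detectionRate(pavMatrix(m))
#' @export
detectionRate <- function(pav, groups = NULL) {
  v <- if (is(pav, "PAVMatrix")) pavValues(pav) else pav
  if (!length(v)) stop("empty matrix")
  rows <- data.frame(group = "overall",
                     called = sum(!is.na(v)),
                     total = length(v))
  if (!is.null(groups)) {
    for (g in unique(groups[rownames(v)])) {
      sub <- v[rownames(v)[groups[rownames(v)] == g], , drop = FALSE]
      rows <- rbind(rows, data.frame(group = g, called = sum(!is.na(sub)),
                                     total = length(sub)))
    }
  }
  rows$rate_percent <- roundHalfUp(100 * rows$called / rows$total)
  rows
}

#' Classify sites by their carrier pattern across germplasm groups
#'
#' Over non-missing cells: \code{fixed_in_all} when every scored accession
#' carries the insertion; \code{line_specific} when exactly one does;
#' \code{group_restricted} when carriers are confined to one group;
#' \code{subgroup_specific} when a subgroup mapping is supplied and carriers
#' are confined to one subgroup; otherwise \code{shared}. Sites with no
#' scored cell in some group are flagged indeterminate.
#'
#' @param pav a \code{\linkS4class{PAVMatrix}} or integer matrix.
#' @param groups named character vector accession -> group (must cover all
#'   accessions).
#' @param subgroups optional named character vector accession -> subgroup.
#' @return data.frame with \code{site}, \code{class}, \code{carriers},
#'   \code{indeterminate}.
#' @export
classifySitesByGroup <- function(pav, groups, subgroups = NULL) {
  v <- if (is(pav, "PAVMatrix")) pavValues(pav) else pav
  if (!all(rownames(v) %in% names(groups)))
    stop("groups must cover all accessions")
  out <- lapply(colnames(v), function(s) {
    col <- v[, s]
    scored <- !is.na(col)
    carriers <- names(col)[scored & col == 1L]
    indet <- any(!tapply(scored, groups[rownames(v)], any))
    cls <- if (!any(scored)) "indeterminate"
    else if (all(col[scored] == 1L)) "fixed_in_all"
    else if (length(carriers) == 1L) "line_specific"
    else if (length(carriers) == 0L) "absent_in_all"
    else {
      gset <- unique(groups[carriers])
      if (length(gset) == 1L) {
        if (!is.null(subgroups) &&
            length(unique(subgroups[carriers])) == 1L)
          "subgroup_specific"
        else "group_restricted"
      } else "shared"
    }
    data.frame(site = s, class = cls, carriers = length(carriers),
               indeterminate = indet, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
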