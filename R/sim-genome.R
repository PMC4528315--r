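## Synthetic-data generator: consensus elements, random genomes, insertion
## planting with TSD duplication, K2P aging of LTR pairs, and reference
## genomes with a ground-truth ledger.

## tRNA used to seed the PBS: the PBS is the reverse complement of the
## primer's 3' terminus. A plant initiator-methionine tRNA stand-in.
PRIMER_TRNA_IMET <-
  "AGCAGAGTGGCGCAGCGGAAGCGTGCTGGGCCCATAACCCAGAGGTCGATGGATCGAAACCATCCTCTGCTACCA"
PBS_MOTIF_LENGTH <- 12L
PPT_MOTIF <- "GAGAGGGGGAGG"   # polypurine tract planted upstream of the 3' LTR

randomDNA <- function(n, gc = 0.46) {
  if (n <= 0L) return("")
  at <- (1 - gc) / 2
  paste(sample(DNA_BASES4, n, replace = TRUE,
               prob = c(at, gc / 2, gc / 2, at)), collapse = "")
}

#' Build a consensus TRIM element
#'
#' Constructs 5'LTR + internal + 3'LTR with the two LTRs identical (the state
#' at integration). When the internal domain is long enough, a PBS motif
#' (reverse complement of the primer tRNA 3' end) is planted immediately
#' downstream of the 5' LTR and a polypurine tract immediately upstream of
#' the 3' LTR.
#'
#' @param config a \code{\linkS4class{TrimSimConfig}}; \code{ltrLength},
#'   \code{internalLength}, \code{gcContent} and \code{seed} are used.
#' @return a \code{\linkS4class{TrimConsensus}}. With the defaults
#'   (230-bp LTRs, 72-bp internal) the element is 532 bp.
#' @examples
#' cons <- makeTrimConsensus(trimSimConfig(seed = 1))
#' length(consensusSequence(cons))  # 532
#' @export
makeTrimConsensus <- function(config) {
  stopifnot(is(config, "TrimSimConfig"))
  L <- config@ltrLength
  I <- config@internalLength
  withSeed(childSeed(config@seed, 1L), {
    ltr <- randomDNA(L, config@gcContent)
    pbs <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(
        substr(PRIMER_TRNA_IMET, nchar(PRIMER_TRNA_IMET) - PBS_MOTIF_LENGTH + 1L,
               nchar(PRIMER_TRNA_IMET)))))
    ppt <- PPT_MOTIF
    motifs_fit <- I >= nchar(pbs) + nchar(ppt)
    internal <- if (motifs_fit) {
      paste0(pbs, randomDNA(I - nchar(pbs) - nchar(ppt), config@gcContent), ppt)
    } else {
      randomDNA(I, config@gcContent)
    }
    seq <- Biostrings::DNAString(paste0(ltr, internal, ltr))
    new("TrimConsensus",
        sequence = seq,
        ltr5 = IRanges::IRanges(1L, L),
        internal = IRanges::IRanges(L + 1L, L + I),
        ltr3 = IRanges::IRanges(L + I + 1L, 2L * L + I),
        pbs = if (motifs_fit) IRanges::IRanges(L + 1L, L + nchar(pbs))
              else IRanges::IRanges(),
        ppt = if (motifs_fit) IRanges::IRanges(L + I - nchar(ppt) + 1L, L + I)
              else IRanges::IRanges())
  })
}

## K2P mutation of a character vector of bases over `t` years at total
## per-site rate r and transition/transversion rate ratio kappa. Uses the
## exact K2P substitution probabilities, so multiple hits are modelled.
mutateK2P <- function(chars, t, r, kappa) {
  n <- length(chars)
  if (t <= 0 || n == 0L) return(chars)
  if (is.infinite(kappa)) {
    beta <- 0
    alpha <- r
  } else {
    beta <- r / (2 * (kappa + 1))
    alpha <- r - 2 * beta
  }
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  pTs <- 0.25 + 0.25 * e1 - 0.5 * e2
  pTvEach <- 0.25 - 0.25 * e1
  u <- runif(n)
  out <- chars
  ts <- u < pTs
  tv1 <- !ts & u < pTs + pTvEach
  tv2 <- !ts & !tv1 & u < pTs + 2 * pTvEach
  if (any(ts))  out[ts]  <- chartr("AGCT", "GATC", chars[ts])
  if (any(tv1)) out[tv1] <- chartr("AGCT", "CCAA", chars[tv1])
  if (any(tv2)) out[tv2] <- chartr("AGCT", "TTGG", chars[tv2])
  out
}

#' Age the LTR pair of a consensus element
#'
#' Mutates each LTR copy independently under the Kimura two-parameter model,
#' with expected per-site substitution load r * ageYears per copy, so the
#' expected divergence between the two copies is K = 2 r T — the inverse of
#' the dating estimator. The internal domain is untouched.
#'
#' @param consensus a \code{\linkS4class{TrimConsensus}}.
#' @param ageYears element age in years (>= 0).
#' @param r substitution rate per site per year.
#' @param tsTvRatio transition/transversion rate ratio (Inf disables
#'   transversions entirely).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{TrimConsensus}} with mutated LTRs.
#' @export
ageLtrPair <- function(consensus, ageYears, r = 1.3e-8, tsTvRatio = 2,
                       seed = 1L) {
  stopifnot(is(consensus, "TrimConsensus"), ageYears >= 0)
  if (ageYears == 0) return(consensus)
  withSeed(seed, {
    s <- strsplit(as.character(consensus@sequence), "")[[1]]
    for (comp in list(consensus@ltr5, consensus@ltr3)) {
      idx <- IRanges::start(comp):IRanges::end(comp)
      s[idx] <- mutateK2P(s[idx], ageYears, r, tsTvRatio)
    }
    out <- consensus
    out@sequence <- Biostrings::DNAString(paste(s, collapse = ""))
    out
  })
}

#' Plant an element into a genome with TSD duplication
#'
#' Inserts \code{element} at a 0-based inter-base offset: the
#' \code{tsdLength} bases immediately left of the insertion point are
#' duplicated so the element ends up flanked by two identical copies of the
#' target-site sequence. Genome length grows by
#' \code{length(element) + tsdLength}.
#'
#' @param genome a \code{DNAStringSet} (one record per chromosome).
#' @param chrom chromosome name.
#' @param pos 0-based inter-base insertion offset, \code{tsdLength <= pos <=}
#'   chromosome length.
#' @param element the sequence to insert (\code{DNAString} or character).
#' @param tsdLength TSD length in bp (0 disables duplication).
#' @return a list with \code{genome} (modified) and \code{record}, a
#'   data.frame truth row: \code{chrom}, \code{insertion_point}, 1-based
#'   \code{start}/\code{end} of the element in the new genome, and
#'   \code{tsd}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGT"))
#' plantInsertion(g, "chr1", 6, "TTTT", tsdLength = 2)$record
#' @export
plantInsertion <- function(genome, chrom, pos, element, tsdLength = 5L) {
  stopifnot(is(genome, "DNAStringSet"), chrom %in% names(genome))
  chromSeq <- genome[[chrom]]
  len <- length(chromSeq)
  pos <- as.integer(pos)
  if (pos < 0L || pos > len)
    stop("insertion point ", pos, " out of range [0, ", len, "]")
  if (tsdLength > pos)
    stop("tsdLength exceeds sequence left of the insertion point")
  element <- as(element, "DNAString")
  tsd <- if (tsdLength > 0L)
    as.character(Biostrings::subseq(chromSeq, pos - tsdLength + 1L, pos))
  else ""
  newSeq <- Biostrings::xscat(
    Biostrings::subseq(chromSeq, 1L, pos),
    element,
    Biostrings::DNAString(tsd),
    if (pos < len) Biostrings::subseq(chromSeq, pos + 1L, len)
    else Biostrings::DNAString(""))
  genome[[chrom]] <- newSeq
  list(genome = genome,
       record = data.frame(
         chrom = chrom,
         insertion_point = pos,
         start = pos + 1L,
         end = pos + length(element),
         tsd = tsd,
         element_length = length(element),
         stringsAsFactors = FALSE))
}

## Assemble the sequence of one planted element, plus the relative (1-based,
## element-forward) coordinates of its LTR copies and any nested insertion.
## category: intact / solo_ltr / truncated; ltrCount >= 2 only for intact;
## nestedLength > 0 plants a foreign segment between internal and 3'-most LTR.
buildElementSeq <- function(consensus, category, ltrCount, ageYears, r,
                            tsTvRatio, gc, nestedLength = 0L, seed = 1L) {
  L <- IRanges::width(consensus@ltr5)
  ltrChars <- strsplit(as.character(consensusLTR(consensus)), "")[[1]]
  internal <- as.character(consensusInternal(consensus))
  withSeed(seed, {
    nLtr <- switch(category, intact = ltrCount, solo_ltr = 1L, truncated = 1L)
    copies <- vapply(seq_len(nLtr), function(i)
      paste(mutateK2P(ltrChars, ageYears, r, tsTvRatio), collapse = ""),
      character(1))
    nested <- if (nestedLength > 0L) randomDNA(nestedLength, gc) else ""
    if (category == "solo_ltr") {
      seq <- copies[1]
      ltrRel <- IRanges::IRanges(1L, L)
      nestedRel <- IRanges::IRanges()
    } else if (category == "truncated") {
      ## 5' LTR + internal domain; the 3' LTR is deleted
      seq <- paste0(copies[1], internal)
      ltrRel <- IRanges::IRanges(1L, L)
      nestedRel <- IRanges::IRanges()
    } else {
      ## LTR - internal - [nested] - LTR - LTR ... (same orientation)
      parts <- c(copies[1], internal,
                 if (nzchar(nested)) nested, copies[-1])
      seq <- paste(parts, collapse = "")
      off <- L + nchar(internal) + nchar(nested)
      ltrRel <- IRanges::IRanges(
        start = c(1L, off + (seq_len(nLtr - 1L) - 1L) * L + 1L),
        width = L)
      nestedRel <- if (nzchar(nested))
        IRanges::IRanges(L + nchar(internal) + 1L, width = nchar(nested))
      else IRanges::IRanges()
    }
    list(seq = seq, ltrRel = ltrRel, nestedRel = nestedRel)
  })
}

## Pick n positions on a multi-chromosome genome, >= margin from the ends,
## >= minSep from each other and from `avoid` positions (per-chromosome list
## of integer vectors). Deterministic under the caller's RNG state.
pickPositions <- function(lengths, n, margin, minSep, avoid = NULL) {
  chroms <- names(lengths)
  chosen <- lapply(chroms, function(x) integer())
  names(chosen) <- chroms
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("capacity error: cannot place ", n,
           " sites with separation ", minSep)
    chrom <- sample(chroms, 1L, prob = lengths)
    lo <- margin
    hi <- lengths[[chrom]] - margin
    if (hi <= lo) next
    pos <- lo + floor(runif(1) * (hi - lo + 1L))
    near <- c(chosen[[chrom]],
              if (!is.null(avoid)) avoid[[chrom]])
    if (length(near) && min(abs(near - pos)) < minSep) next
    chosen[[chrom]] <- c(chosen[[chrom]], as.integer(pos))
    placed <- placed + 1L
  }
  out <- do.call(rbind, lapply(chroms, function(ch)
    if (length(chosen[[ch]]))
      data.frame(chrom = ch, pos = sort(chosen[[ch]]))
    else NULL))
  out[order(match(out$chrom, chroms), out$pos), , drop = FALSE]
}

#' Simulate a reference genome with planted TRIM elements
#'
#' Generates an i.i.d. background genome (so flanking sequence is effectively
#' unique) and plants elements of known category, age, strand, and TSD,
#' including multi-LTR tandem arrangements and one nested foreign insertion.
#' Every planted feature is recorded in a ground-truth ledger.
#'
#' @param config a \code{\linkS4class{TrimSimConfig}}.
#' @param nIntact,nSolo,nTruncated element counts per category.
#' @param extraLtrCounts LTR counts for tandem intact elements; e.g.
#'   \code{c(3, 4)} turns the first two intact elements into 3- and 4-LTR
#'   tandems (the remainder get the canonical 2).
#' @param nNested how many intact elements receive a nested foreign
#'   insertion (placed between the internal domain and the 3'-most LTR).
#' @param nestedLength nested-insertion length in bp.
#' @param ages ages in years for the planted elements, recycled; defaults to
#'   a 0-3 Myr ladder.
#' @return a \code{\linkS4class{TrimSimulation}}.
#' @export
makeReferenceGenome <- function(config,
                                nIntact = 6L, nSolo = 3L, nTruncated = 3L,
                                extraLtrCounts = c(3L, 4L),
                                nNested = 1L,
                                nestedLength = 689L,
                                ages = NULL) {
  stopifnot(is(config, "TrimSimConfig"))
  consensus <- makeTrimConsensus(config)
  n <- nIntact + nSolo + nTruncated
  categories <- c(rep("intact", nIntact), rep("solo_ltr", nSolo),
                  rep("truncated", nTruncated))
  ltrCounts <- ifelse(categories == "intact", 2L, 1L)
  if (nIntact > 0L && length(extraLtrCounts))
    ltrCounts[seq_len(min(length(extraLtrCounts), nIntact))] <-
      as.integer(extraLtrCounts)[seq_len(min(length(extraLtrCounts), nIntact))]
  nestedLens <- integer(n)
  if (nNested > 0L && nIntact > 0L) {
    ## nest into the last intact elements so tandems stay nest-free
    idx <- seq(to = nIntact, length.out = min(nNested, nIntact))
    nestedLens[idx] <- as.integer(nestedLength)
  }
  if (is.null(ages))
    ages <- rep(c(0, 5e5, 1e6, 2e6, 3e6), length.out = n)
  ages <- rep_len(ages, n)

  withSeed(childSeed(config@seed, 2L), {
    lens <- setNames(config@chromosomeLengths,
                     paste0("chr", seq_along(config@chromosomeLengths)))
    genome <- Biostrings::DNAStringSet(
      vapply(lens, randomDNA, character(1), gc = config@gcContent))
    names(genome) <- names(lens)

    if (n > 0L) {
      sitedf <- pickPositions(lens, n, margin = 1500L, minSep = 3000L)
      strands <- rep(c("+", "-"), length.out = n)
      built <- lapply(seq_len(n), function(i)
        buildElementSeq(consensus, categories[i], ltrCounts[i], ages[i],
                        config@substitutionRate, config@tsTvRatio,
                        config@gcContent, nestedLens[i],
                        seed = childSeed(config@seed, 100L + i)))
      ## order of `sitedf` is genomic; keep element attributes in that order
      ord <- sample(n)  # shuffle which element lands at which site
      truth <- vector("list", n)
      ## plant per chromosome from right to left so coordinates stay valid
      for (ch in names(genome)) {
        rows <- which(sitedf$chrom == ch)
        for (k in rev(seq_along(rows))) {
          i <- rows[k]
          e <- built[[ord[i]]]
          strand <- strands[ord[i]]
          elemSeq <- Biostrings::DNAString(e$seq)
          if (strand == "-")
            elemSeq <- Biostrings::reverseComplement(elemSeq)
          p <- plantInsertion(genome, ch, sitedf$pos[i], elemSeq,
                              config@tsdLength)
          genome <- p$genome
          truth[[i]] <- cbind(p$record,
            data.frame(category = categories[ord[i]],
                       ltr_count = ltrCounts[ord[i]],
                       age_years = ages[ord[i]],
                       strand = strand,
                       element_index = ord[i],
                       stringsAsFactors = FALSE))
        }
      }
      truthdf <- do.call(rbind, truth)
      ## shift to final coordinates: insertions upstream on the same
      ## chromosome each add element_length + tsd
      truthdf <- truthdf[order(match(truthdf$chrom, names(genome)),
                               truthdf$insertion_point), ]
      shift <- unlist(lapply(split(
        truthdf$element_length + config@tsdLength,
        factor(truthdf$chrom, levels = names(genome))),
        function(w) if (!length(w)) integer(0)
                    else cumsum(c(0L, head(w, -1L)))), use.names = FALSE)
      truthdf$start <- truthdf$start + shift
      truthdf$end <- truthdf$end + shift

      ltrIv <- vapply(seq_len(nrow(truthdf)), function(j) {
        e <- built[[truthdf$element_index[j]]]
        len <- truthdf$element_length[j]
        rel <- e$ltrRel
        if (truthdf$strand[j] == "-")
          rel <- IRanges::IRanges(len - IRanges::end(rel) + 1L,
                                  len - IRanges::start(rel) + 1L)
        rel <- sortByStart(rel)
        paste(IRanges::start(rel) + truthdf$start[j] - 1L,
              IRanges::end(rel) + truthdf$start[j] - 1L,
              sep = "-", collapse = ",")
      }, character(1))
      nestedIv <- vapply(seq_len(nrow(truthdf)), function(j) {
        e <- built[[truthdf$element_index[j]]]
        len <- truthdf$element_length[j]
        rel <- e$nestedRel
        if (!length(rel)) return(NA_character_)
        if (truthdf$strand[j] == "-")
          rel <- IRanges::IRanges(len - IRanges::end(rel) + 1L,
                                  len - IRanges::start(rel) + 1L)
        paste(IRanges::start(rel) + truthdf$start[j] - 1L,
              IRanges::end(rel) + truthdf$start[j] - 1L, sep = "-")
      }, character(1))

      elements <- GenomicRanges::GRanges(
        seqnames = truthdf$chrom,
        ranges = IRanges::IRanges(truthdf$start, truthdf$end),
        strand = truthdf$strand,
        element_id = sprintf("E%03d", seq_len(nrow(truthdf))),
        category = truthdf$category,
        ltr_count = truthdf$ltr_count,
        age_years = truthdf$age_years,
        tsd = truthdf$tsd,
        insertion_point = truthdf$insertion_point,
        ltr_intervals = ltrIv,
        nested = nestedIv)
    } else {
      elements <- GenomicRanges::GRanges()
    }
    new("TrimSimulation", genome = genome, elements = elements,
        consensus = consensus, config = config)
  })
}

#' Simulate an accession panel with group-structured insertion polymorphism
#'
#' Builds per-accession genomes on top of a reference simulation. Insertion
#' sites come in three sharing classes: fixed sites carried by every
#' accession, group-private sites carried by all members of exactly one
#' germplasm group, and line-private sites carried by exactly one accession.
#' Planted elements are newly integrated intact copies (identical LTRs).
#'
#' @param reference a \code{\linkS4class{TrimSimulation}}.
#' @param config a \code{\linkS4class{TrimSimConfig}} (defaults to the one in
#'   \code{reference}); \code{groupSizes} and the three site-class counts
#'   define the panel.
#' @param seed RNG seed (defaults to the config seed).
#' @return a \code{\linkS4class{TrimPanel}}; \code{panelGenotypes} holds the
#'   truth carrier matrix with no missing values.
#' @export
buildPopulation <- function(reference, config = simConfig(reference),
                            seed = config@seed) {
  stopifnot(is(reference, "TrimSimulation"))
  gs <- config@groupSizes
  if (!length(gs) || any(gs <= 0L)) stop("groupSizes must be non-empty")
  groups <- rep(names(gs), gs)
  accs <- unlist(lapply(names(gs), function(g)
    paste0(g, "_", seq_len(gs[[g]]))))
  names(groups) <- accs

  nF <- config@nFixedSites
  nG <- config@nGroupPrivateSites
  nL <- config@nLinePrivateSites
  nSites <- nF + nG + nL

  withSeed(childSeed(seed, 3L), {
    genome <- simGenome(reference)
    lens <- setNames(Biostrings::width(genome), names(genome))
    avoid <- lapply(names(genome), function(ch) {
      e <- simElements(reference)
      as.integer(IRanges::start(
        GenomicRanges::ranges(e[GenomicRanges::seqnames(e) == ch])))
    })
    names(avoid) <- names(genome)
    sitedf <- pickPositions(lens, nSites, margin = 1000L, minSep = 2500L,
                            avoid = avoid)
    classes <- c(rep("fixed", nF),
                 rep("group_private", nG),
                 rep("line_private", nL))
    sitedf$class <- sample(classes)  # decouple class from genomic order
    sitedf$site_id <- sprintf("S%03d", seq_len(nSites))
    gpIdx <- which(sitedf$class == "group_private")
    sitedf$owner <- NA_character_
    sitedf$owner[gpIdx] <- rep(names(gs), length.out = length(gpIdx))
    lpIdx <- which(sitedf$class == "line_private")
    sitedf$owner[lpIdx] <- rep(accs, length.out = length(lpIdx))

    ## truth genotypes
    geno <- matrix(0L, length(accs), nSites,
                   dimnames = list(accs, sitedf$site_id))
    for (j in seq_len(nSites)) {
      geno[, j] <- switch(sitedf$class[j],
        fixed = 1L,
        group_private = as.integer(groups == sitedf$owner[j]),
        line_private = as.integer(accs == sitedf$owner[j]))
    }

    ## panel insertions are newly transposed intact copies: identical LTRs
    elemSeq <- Biostrings::DNAString(as.character(
      consensusSequence(simConsensus(reference))))
    tsd <- config@tsdLength
    sitedf$tsd_seq <- vapply(seq_len(nSites), function(j) {
      ch <- genome[[sitedf$chrom[j]]]
      as.character(Biostrings::subseq(ch, sitedf$pos[j] - tsd + 1L,
                                      sitedf$pos[j]))
    }, character(1))

    genomes <- lapply(accs, function(a) {
      g <- genome
      carried <- which(geno[a, ] == 1L)
      df <- sitedf[carried, , drop = FALSE]
      df <- df[order(match(df$chrom, names(g)), -df$pos), , drop = FALSE]
      for (j in seq_len(nrow(df)))
        g <- plantInsertion(g, df$chrom[j], df$pos[j], elemSeq, tsd)$genome
      g
    })
    names(genomes) <- accs

    sites <- data.frame(site_id = sitedf$site_id,
                        chrom = sitedf$chrom,
                        pos = sitedf$pos,
                        class = sitedf$class,
                        owner = sitedf$owner,
                        tsd = sitedf$tsd_seq,
                        stringsAsFactors = FALSE)
    new("TrimPanel", reference = reference, accessionGenomes = genomes,
        groups = groups, sites = sites, genotypes = geno)
  })
}
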