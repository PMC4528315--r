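test_that("consensus element has the expected structure and dimensions", {
  cfg <- trimSimConfig(seed = 3L)
  cons <- makeTrimConsensus(cfg)
  seq <- consensusSequence(cons)
  expect_equal(length(seq), 532L)           # 2 x 230 + 72
  expect_equal(length(consensusLTR(cons)), 230L)
  expect_equal(length(consensusInternal(cons)), 72L)
  ## the two LTRs are identical at integration
  expect_equal(as.character(Biostrings::subseq(seq, 1, 230)),
               as.character(Biostrings::subseq(seq, 303, 532)))
  ## PBS sits right after the 5' LTR, PPT right before the 3' LTR
  expect_equal(IRanges::start(cons@pbs), 231L)
  expect_equal(IRanges::end(cons@ppt), 302L)
  ppt <- as.character(Biostrings::subseq(seq, IRanges::start(cons@ppt),
                                         IRanges::end(cons@ppt)))
  expect_false(grepl("[CT]", ppt))          # purine-only tract
})

test_that("degenerate consensus dimensions are honoured", {
  cfg <- trimSimConfig(seed = 1L, ltrLength = 1L, internalLength = 1L)
  cons <- makeTrimConsensus(cfg)
  expect_equal(length(consensusSequence(cons)), 3L)
  expect_equal(as.character(consensusLTR(cons)),
               as.character(Biostrings::subseq(consensusSequence(cons), 3, 3)))
})

test_that("consensus generation is seed-deterministic", {
  a <- makeTrimConsensus(trimSimConfig(seed = 7L))
  b <- makeTrimConsensus(trimSimConfig(seed = 7L))
  expect_identical(as.character(consensusSequence(a)),
                   as.character(consensusSequence(b)))
  c <- makeTrimConsensus(trimSimConfig(seed = 8L))
  expect_false(identical(as.character(consensusSequence(a)),
                         as.character(consensusSequence(c))))
})

test_that("plantInsertion duplicates the target site and keeps the books", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
  p <- plantInsertion(g, "chr1", 10L, "TTTTT", tsdLength = 3L)
  expect_equal(Biostrings::width(p$genome)[[1]],
               20L + 5L + 3L)               # element + TSD
  rec <- p$record
  expect_equal(rec$tsd, "TAC")   # the 3 bases immediately left of offset 10
  new <- as.character(p$genome[[1]])
  expect_equal(substr(new, rec$start, rec$end), "TTTTT")
  expect_equal(substr(new, rec$start - 3, rec$start - 1),
               substr(new, rec$end + 1, rec$end + 3))
  ## zero-length TSD: flanks unchanged
  p0 <- plantInsertion(g, "chr1", 10L, "TTTTT", tsdLength = 0L)
  expect_equal(as.character(p0$genome[[1]]),
               paste0(substr("ACGTACGTACGTACGTACGT", 1, 10), "TTTTT",
                      substr("ACGTACGTACGTACGTACGT", 11, 20)))
  expect_error(plantInsertion(g, "chr1", 25L, "TT"), "out of range")
  expect_error(plantInsertion(g, "chr1", 2L, "TT", tsdLength = 5L),
               "tsdLength")
})

test_that("aging at t = 0 leaves LTRs identical; infinite ts/tv kills Q", {
  cons <- makeTrimConsensus(trimSimConfig(seed = 5L))
  aged0 <- ageLtrPair(cons, 0, seed = 1L)
  expect_identical(as.character(consensusSequence(aged0)),
                   as.character(consensusSequence(cons)))
  for (s in 1:25) {
    aged <- ageLtrPair(cons, 3e6, tsTvRatio = Inf, seed = s)
    seq <- consensusSequence(aged)
    pq <- pqOracle(as.character(Biostrings::subseq(seq, 1, 230)),
                   as.character(Biostrings::subseq(seq, 303, 532)))
    expect_identical(unname(pq["Q"]), 0)    # transversions disabled
  }
})

test_that("aged LTR pairs recover K = 2rT on average", {
  cons <- makeTrimConsensus(trimSimConfig(seed = 5L))
  reps <- 400L
  Ks <- vapply(seq_len(reps), function(s) {
    aged <- ageLtrPair(cons, 1e6, r = 1.3e-8, seed = s)
    seq <- consensusSequence(aged)
    kimura2p(as.character(Biostrings::subseq(seq, 1, 230)),
             as.character(Biostrings::subseq(seq, 303, 532)))$K
  }, numeric(1))
  se <- stats::sd(Ks) / sqrt(reps)
  expect_lt(abs(mean(Ks) - 0.026), 3 * se)
})

test_that("reference truth ledger matches the emitted genome", {
  fx <- refFixture()
  tr <- simElements(fx$sim)
  g <- simGenome(fx$sim)
  expect_length(tr, 12L)
  expect_setequal(unique(tr$category), c("intact", "solo_ltr", "truncated"))
  expect_true(all(c(3L, 4L) %in% tr$ltr_count))
  for (i in seq_along(tr)) {
    ch <- as.character(GenomicRanges::seqnames(tr)[i])
    s <- GenomicRanges::start(tr)[i]
    e <- GenomicRanges::end(tr)[i]
    ## TSD appears verbatim immediately flanking both element ends
    expect_equal(as.character(Biostrings::subseq(g[[ch]], s - 5L, s - 1L)),
                 tr$tsd[i])
    expect_equal(as.character(Biostrings::subseq(g[[ch]], e + 1L, e + 5L)),
                 tr$tsd[i])
  }
})

test_that("panel truth matrix obeys the sharing-class definitions", {
  cfg <- trimSimConfig(seed = 31L,
                       chromosomeLengths = c(25000L, 25000L, 25000L),
                       groupSizes = c(g1 = 4L, g2 = 4L, g3 = 4L),
                       nFixedSites = 5L, nGroupPrivateSites = 3L,
                       nLinePrivateSites = 4L)
  sim <- makeReferenceGenome(cfg, nIntact = 1L, nSolo = 0L, nTruncated = 0L,
                             extraLtrCounts = integer(), nNested = 0L)
  panel <- buildPopulation(sim, cfg)
  geno <- panelGenotypes(panel)
  sites <- panelSites(panel)
  groups <- panelGroups(panel)
  expect_false(anyNA(geno))                 # truth has no missing values
  for (j in seq_len(nrow(sites))) {
    cs <- sum(geno[, j])
    if (sites$class[j] == "fixed") expect_equal(cs, 12L)
    if (sites$class[j] == "line_private") expect_equal(cs, 1L)
    if (sites$class[j] == "group_private") {
      members <- names(groups)[groups == sites$owner[j]]
      expect_equal(sort(rownames(geno)[geno[, j] == 1L]), sort(members))
    }
  }
  ## carrier accessions hold the planted element sequence at the site
  elem <- as.character(consensusSequence(simConsensus(sim)))
  acc <- rownames(geno)[1]
  carried <- which(geno[acc, ] == 1L)
  gacc <- panelGenomes(panel)[[acc]]
  for (j in carried[1:2]) {
    found <- Biostrings::vcountPattern(elem, gacc)
    expect_gte(sum(found), 1L)
  }
})

test_that("population build is byte-deterministic under a fixed seed", {
  cfg <- trimSimConfig(seed = 41L, chromosomeLengths = c(20000L, 20000L,
                                                         20000L),
                       groupSizes = c(a = 2L, b = 2L),
                       nFixedSites = 2L, nGroupPrivateSites = 2L,
                       nLinePrivateSites = 1L)
  sim <- makeReferenceGenome(cfg, nIntact = 1L, nSolo = 0L, nTruncated = 0L,
                             extraLtrCounts = integer(), nNested = 0L)
  p1 <- buildPopulation(sim, cfg)
  p2 <- buildPopulation(sim, cfg)
  expect_identical(lapply(panelGenomes(p1), as.character),
                   lapply(panelGenomes(p2), as.character))
  expect_identical(panelGenotypes(p1), panelGenotypes(p2))
})

test_that("read simulation respects coverage, exactness, and determinism", {
  cfg <- trimSimConfig(seed = 51L, chromosomeLengths = 100000L,
                       coverage = 20, errorRate = 0, readLength = 150L)
  sim <- makeReferenceGenome(cfg, nIntact = 0L, nSolo = 0L, nTruncated = 0L)
  g <- simGenome(sim)
  rd <- simulateReads(g, cfg)
  n <- length(rd$r1)
  expected <- 20 * 100000 / 300
  expect_lt(abs(n - expected), 3 * sqrt(expected))   # Poisson sampling
  ## error-free reads are exact substrings of the genome (fwd or revcomp)
  idx <- sample(n, 25L)
  for (i in idx) {
    expect_equal(Biostrings::vcountPattern(rd$r1[[i]], g)[1] +
                 Biostrings::vcountPattern(
                   Biostrings::reverseComplement(rd$r1[[i]]), g)[1], 1L)
  }
  ## origins ledger points at the true source interval
  org <- rd$origins[rd$origins$mate == 1L, ][idx, ]
  for (k in seq_len(nrow(org))) {
    src <- Biostrings::subseq(g[[org$chrom[k]]], org$start[k], org$end[k])
    expect_equal(as.character(src), as.character(rd$r1[[org$read_id[k]]]))
  }
  ## zero coverage, zero reads
  cfg0 <- trimSimConfig(seed = 51L, chromosomeLengths = 10000L, coverage = 0)
  expect_length(simulateReads(simGenome(sim), cfg0)$r1, 0L)
  ## byte-identical FASTQ under the same seed
  rd2 <- simulateReads(g, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeReadsFastq(rd, f1)
  writeReadsFastq(rd2, f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
})
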