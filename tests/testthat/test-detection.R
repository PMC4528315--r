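## A small hand-built carrier genome used across the detection tests:
## one intact element planted at a known offset with a 5-bp TSD.
detectionFixture <- function() fixture("detect", function() {
  cfg <- trimSimConfig(seed = 111L, chromosomeLengths = 8000L)
  cons <- makeTrimConsensus(cfg)
  ref <- makeReferenceGenome(cfg, nIntact = 0L, nSolo = 0L, nTruncated = 0L)
  genome <- simGenome(ref)
  pos <- 3000L
  p <- plantInsertion(genome, "chr1", pos, consensusSequence(cons), 5L)
  list(cfg = cfg, cons = cons, reference = genome, carrier = p$genome,
       pos = pos, tsd = p$record$tsd,
       elemLen = length(consensusSequence(cons)))
})

carrierRead <- function(fx, centre, len = 150L) {
  Biostrings::subseq(fx$carrier[["chr1"]], centre - len %/% 2L,
                     centre - len %/% 2L + len - 1L)
}

test_that("junction-read selection applies the three-step rules", {
  fx <- detectionFixture()
  ltr <- consensusLTR(fx$cons)
  ## read spanning the left junction: 75 bp flank + 75 bp LTR start
  left <- carrierRead(fx, fx$pos)
  ## read spanning the right junction (element end | TSD + ref)
  right <- carrierRead(fx, fx$pos + fx$elemLen)
  ## read entirely inside the LTR: positional information absent
  pure <- Biostrings::subseq(fx$carrier[["chr1"]], fx$pos + 30L,
                             fx$pos + 179L)
  ## read with only 19 bp of LTR terminus: below the minimum match
  short <- Biostrings::subseq(fx$carrier[["chr1"]], fx$pos - 131L,
                              fx$pos + 19L)
  reads <- Biostrings::DNAStringSet(list(left = left, right = right,
                                         pure = pure, short = short))
  jr <- selectJunctionReads(reads, ltr)
  expect_setequal(jr$read_id, c("left", "right"))
  expect_equal(jr$flank_side[jr$read_id == "left"], "left")
  expect_equal(jr$flank_side[jr$read_id == "right"], "right")
  ## read covers pos-75..pos+74; the element begins at pos+1
  expect_equal(jr$ltr_match_length[jr$read_id == "left"], 74L)
  ## reverse-complemented reads are recognised identically
  jrRc <- selectJunctionReads(Biostrings::reverseComplement(reads), ltr)
  expect_setequal(jrRc$read_id, c("left", "right"))
  expect_equal(sort(jrRc$flank_sequence), sort(jr$flank_sequence))
})

test_that("flank mapping distinguishes unique, ambiguous, and unmapped", {
  fx <- detectionFixture()
  flank <- Biostrings::subseq(fx$reference[["chr1"]], 1001L, 1060L)
  m <- mapFlankUnique(flank, fx$reference)
  expect_equal(m$status, "unique")
  expect_equal(m$start, 1001L)
  expect_equal(m$strand, "+")
  ## reverse-strand mapping reports the same locus on '-'
  mRc <- mapFlankUnique(Biostrings::reverseComplement(flank), fx$reference)
  expect_equal(mRc$status, "unique")
  expect_equal(mRc$start, 1001L)
  expect_equal(mRc$strand, "-")
  ## duplicated segment: ambiguous by construction
  dupRef <- Biostrings::DNAStringSet(c(
    chr1 = paste0(as.character(fx$reference[["chr1"]]),
                  as.character(flank))))
  expect_equal(mapFlankUnique(flank, dupRef)$status, "ambiguous")
  ## foreign sequence: unmapped
  expect_equal(mapFlankUnique(strrep("ACGT", 15), fx$reference)$status,
               "unmapped")
})

test_that("calls reconstruct the insertion offset and TSD from junction clusters", {
  fx <- detectionFixture()
  ltr <- consensusLTR(fx$cons)
  centres <- c(fx$pos - 20L, fx$pos, fx$pos + 15L,
               fx$pos + fx$elemLen, fx$pos + fx$elemLen + 20L)
  reads <- Biostrings::DNAStringSet(lapply(centres, function(cc)
    carrierRead(fx, cc)))
  names(reads) <- paste0("r", seq_along(reads))
  calls <- detectInsertions(reads, ltr, fx$reference)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, fx$pos)
  expect_equal(calls$tsd, fx$tsd)           # left/right offset = 5 bp
  expect_equal(nchar(calls$tsd), 5L)
  expect_equal(calls$status, "non_reference")
  ## conservation of evidence: support equals the junction-read count
  jr <- selectJunctionReads(reads, ltr)
  mapped <- mapJunctionReads(jr, fx$reference)
  expect_equal(calls$support_left + calls$support_right, nrow(mapped))
  ## detection is invariant under read-order permutation
  perm <- reads[c(4, 2, 5, 1, 3)]
  callsPerm <- detectInsertions(perm, ltr, fx$reference)
  expect_equal(callsPerm, calls)
  ## zero junction reads give an empty call table
  none <- Biostrings::DNAStringSet(c(x = strrep("ACGT", 37)))
  expect_equal(nrow(detectInsertions(none, ltr, fx$reference)), 0L)
})

test_that("calls overlapping annotated reference elements are labelled reference", {
  fx <- detectionFixture()
  ltr <- consensusLTR(fx$cons)
  reads <- Biostrings::DNAStringSet(list(a = carrierRead(fx, fx$pos)))
  fakeAnn <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(fx$pos - 5L,
                                                     fx$pos + 500L))
  calls <- detectInsertions(reads, ltr, fx$reference, fakeAnn)
  expect_equal(calls$status, "reference")
})

test_that("sharing summary reproduces carrier-count arithmetic", {
  ## the printed worked example: 52 line-specific, 13 in two lines,
  ## 22 in three or more, of 87 total
  sites <- sprintf("chr1:%d", seq_len(87) * 1000L)
  lines <- list(l1 = character(), l2 = character(), l3 = character())
  lines$l1 <- sites[1:52]                      # private to line 1
  lines$l2 <- sites[53:65]                     # shared by lines 2+3
  lines$l3 <- c(sites[53:65], sites[66:87])
  lines$l4 <- sites[66:87]                     # 22 sites in 3 lines
  lines$l5 <- sites[66:87]
  sh <- sharingSummary(lines)
  expect_equal(attr(sh, "total"), 87L)
  expect_equal(sh$count, c(52L, 13L, 22L))
  expect_equal(sh$percent, c(60, 15, 25))
  ## degenerate: one site in one line
  sh1 <- sharingSummary(list(only = "chr1:5"))
  expect_equal(sh1$percent, c(100, 0, 0))
  ## panel truth tally oracle
  fxp <- panelFixture()
  geno <- panelGenotypes(fxp$panel)
  sites <- panelSites(fxp$panel)
  byLine <- lapply(rownames(geno), function(a)
    sprintf("%s:%d", sites$chrom, sites$pos)[geno[a, ] == 1L])
  names(byLine) <- rownames(geno)
  sh2 <- sharingSummary(byLine)
  carriers <- colSums(geno)
  expect_equal(sh2$count,
               c(sum(carriers == 1L), sum(carriers == 2L),
                 sum(carriers >= 3L)))
})
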