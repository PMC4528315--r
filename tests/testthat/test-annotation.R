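parseIntervals <- function(x) {
  parts <- strsplit(strsplit(x, ",")[[1]], "-")
  IRanges::IRanges(as.integer(sapply(parts, `[`, 1)),
                   as.integer(sapply(parts, `[`, 2)))
}

test_that("scan of a single planted intact element yields 2 LTR + 1 internal hit", {
  cfg <- trimSimConfig(seed = 61L, chromosomeLengths = 20000L)
  sim <- makeReferenceGenome(cfg, nIntact = 1L, nSolo = 0L, nTruncated = 0L,
                             extraLtrCounts = integer(), nNested = 0L,
                             ages = 1e6)
  hits <- scanGenome(simGenome(sim), asTrimModel(simConsensus(sim)))
  expect_equal(sum(hits$component == "ltr"), 2L)
  expect_equal(sum(hits$component == "internal"), 1L)
  tr <- simElements(sim)
  ltrTruth <- parseIntervals(tr$ltr_intervals)
  ltrHits <- hits[hits$component == "ltr", ]
  expect_equal(sort(ltrHits$start), sort(IRanges::start(ltrTruth)))
  expect_equal(sort(ltrHits$end), sort(IRanges::end(ltrTruth)))
})

test_that("an element-free random genome yields zero hits, matching an exhaustive oracle", {
  cfg <- trimSimConfig(seed = 71L, chromosomeLengths = 20000L)
  sim <- makeReferenceGenome(cfg, nIntact = 0L, nSolo = 0L, nTruncated = 0L)
  model <- asTrimModel(simConsensus(sim))
  hits <- scanGenome(simGenome(sim), model)
  expect_equal(nrow(hits), 0L)
  ## oracle: edit-distance-bounded exhaustive search of the full consensus
  g <- simGenome(sim)[[1]]
  ltr <- model@ltrConsensus
  budget <- floor((1 - model@minIdentity) * length(ltr))
  oracle <- Biostrings::matchPattern(ltr, g, max.mismatch = budget,
                                     with.indels = TRUE)
  expect_length(oracle, 0L)
})

test_that("scan agrees with an edit-distance oracle on planted full-length copies", {
  cfg <- trimSimConfig(seed = 81L, chromosomeLengths = 20000L)
  sim <- makeReferenceGenome(cfg, nIntact = 2L, nSolo = 1L, nTruncated = 0L,
                             extraLtrCounts = integer(), nNested = 0L,
                             ages = c(0, 2e6, 1e6))
  model <- asTrimModel(simConsensus(sim))
  g <- simGenome(sim)
  hits <- scanGenome(g, model)
  ltrHits <- hits[hits$component == "ltr", ]
  for (ch in names(g)) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") g[[ch]] else
        Biostrings::reverseComplement(g[[ch]])
      budget <- floor(0.12 * length(model@ltrConsensus))
      m <- Biostrings::matchPattern(model@ltrConsensus, subject,
                                    max.mismatch = budget,
                                    with.indels = TRUE)
      starts <- IRanges::start(m)
      if (strand == "-")
        starts <- length(g[[ch]]) - IRanges::end(m) + 1L
      mine <- ltrHits$start[ltrHits$chrom == ch & ltrHits$strand == strand]
      ## every oracle copy is found (within a small boundary slack)
      for (s in starts)
        expect_true(any(abs(mine - s) <= 3L))
    }
  }
})

test_that("annotation round-trips every planted element exactly", {
  fx <- refFixture()
  tr <- simElements(fx$sim)
  ann <- fx$ann
  expect_equal(length(ann), length(tr))
  trDf <- as.data.frame(tr)[, c("seqnames", "start", "end", "strand",
                                "category", "ltr_count", "tsd")]
  annDf <- as.data.frame(ann)[, c("seqnames", "start", "end", "strand",
                                  "category", "ltr_count", "tsd")]
  o1 <- order(trDf$seqnames, trDf$start)
  o2 <- order(annDf$seqnames, annDf$start)
  expect_equal(annDf[o2, ], trDf[o1, ], ignore_attr = TRUE)
  ## category counts partition the total
  expect_equal(sum(table(ann$category)), length(ann))
  ## the 3- and 4-LTR tandems are recovered with their LTR counts
  expect_setequal(ann$ltr_count[ann$category == "intact"],
                  tr$ltr_count[tr$category == "intact"])
  ## nested insertion is recorded where planted
  expect_equal(ann$nested[!is.na(ann$nested)],
               tr$nested[!is.na(tr$nested)])
})

test_that("annotating the reverse complement mirrors coordinates and strands", {
  cfg <- trimSimConfig(seed = 91L, chromosomeLengths = 15000L)
  sim <- makeReferenceGenome(cfg, nIntact = 1L, nSolo = 1L, nTruncated = 0L,
                             extraLtrCounts = integer(), nNested = 0L)
  g <- simGenome(sim)
  model <- asTrimModel(simConsensus(sim))
  ann <- annotateGenome(g, model)
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  annRc <- annotateGenome(rc, model)
  L <- Biostrings::width(g)[1]
  expect_equal(sort(L - GenomicRanges::end(annRc) + 1L),
               sort(GenomicRanges::start(ann)))
  flip <- c("+" = "-", "-" = "+")
  o1 <- order(GenomicRanges::start(ann))
  o2 <- order(L - GenomicRanges::end(annRc) + 1L)
  expect_equal(unname(flip[as.character(GenomicRanges::strand(annRc))[o2]]),
               as.character(GenomicRanges::strand(ann))[o1])
  expect_equal(annRc$category[o2], ann$category[o1])
})

test_that("TSD detection requires identical flanking k-mers", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0("GTGTC", "AAAATTTT", "GTGTC",
                                                "CCCC")))
  expect_equal(detectTsd(g, "chr1", 6L, 13L, 5L), "GTGTC")
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0("GTGTC", "AAAATTTT", "GTGTA",
                                                 "CCCC")))
  expect_true(is.na(detectTsd(g2, "chr1", 6L, 13L, 5L)))
  ## chromosome edge: NA, not an error
  expect_true(is.na(detectTsd(g, "chr1", 2L, 13L, 5L)))
})

test_that("chromosome density reproduces printed-table arithmetic", {
  d <- chromosomeDensity(c(chr10 = 27, chr6 = 12, chrX = 0),
                         c(chr10 = 143, chr6 = 161, chrX = 50))
  expect_equal(d$density, c(0.18, 0.07, 0.00))
  expect_error(chromosomeDensity(c(a = 1), c(a = 0)), "positive")
})
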