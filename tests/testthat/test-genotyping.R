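genotypeFixture <- function() fixture("geno", function() {
  cfg <- trimSimConfig(seed = 121L, chromosomeLengths = 10000L,
                       coverage = 10, errorRate = 0)
  cons <- makeTrimConsensus(cfg)
  ref <- simGenome(makeReferenceGenome(cfg, nIntact = 0L, nSolo = 0L,
                                       nTruncated = 0L))
  pos <- 5000L
  carrier <- plantInsertion(ref, "chr1", pos, consensusSequence(cons),
                            5L)$genome
  fl <- extractSiteFlanks(ref, "chr1", pos, consensusLTR(cons),
                          tsdLength = 5L, siteId = "S1")
  list(cfg = cfg, cons = cons, ref = ref, carrier = carrier, pos = pos,
       flanks = fl)
})

test_that("site flanks and allele signatures are exact and deterministic", {
  fx <- genotypeFixture()
  fl <- fx$flanks
  ## left flank is reference[pos-150, pos)
  expect_equal(fl$left_flank,
               as.character(Biostrings::subseq(fx$ref[["chr1"]],
                                               fx$pos - 149L, fx$pos)))
  expect_equal(nchar(fl$left_flank), 150L)
  ## byte-identical regeneration
  fl2 <- extractSiteFlanks(fx$ref, "chr1", fx$pos,
                           consensusLTR(fx$cons), tsdLength = 5L,
                           siteId = "S1")
  expect_identical(fl, fl2)
  ## presence signatures occur verbatim in the carrier, not the reference
  pl <- paste0(substr(fl$junction_present_left$left, 131, 150),
               substr(fl$junction_present_left$right, 1, 20))
  expect_equal(Biostrings::vcountPattern(pl, fx$carrier)[1], 1L)
  expect_equal(Biostrings::vcountPattern(pl, fx$ref)[1], 0L)
  pr <- paste0(substr(fl$junction_present_right$left,
                      nchar(fl$junction_present_right$left) - 19,
                      nchar(fl$junction_present_right$left)),
               substr(fl$junction_present_right$right, 1, 20))
  expect_equal(Biostrings::vcountPattern(pr, fx$carrier)[1], 1L)
  ## absence signature: the converse
  ab <- paste0(substr(fl$junction_absent$left, 131, 150),
               substr(fl$junction_absent$right, 1, 20))
  expect_equal(Biostrings::vcountPattern(ab, fx$ref)[1], 1L)
  expect_equal(Biostrings::vcountPattern(ab, fx$carrier)[1], 0L)
})

test_that("genotype calls follow read evidence: carrier 1, non-carrier 0, no reads ?", {
  fx <- genotypeFixture()
  mkReads <- function(genome, seed)
    with(simulateReads(genome, fx$cfg, seed = seed), c(r1, r2))
  gC <- genotypeSite(mkReads(fx$carrier, 1L), fx$flanks)
  expect_equal(gC$value, 1L)
  expect_gte(gC$supportPresent, 1L)
  expect_equal(gC$supportAbsent, 0L)
  gN <- genotypeSite(mkReads(fx$ref, 2L), fx$flanks)
  expect_equal(gN$value, 0L)
  ## reads that never overlap the site are uninformative
  far <- randomReads(50L, 150L, seed = 3L)
  gF <- genotypeSite(far, fx$flanks)
  expect_true(is.na(gF$value))
  expect_false(gF$conflict)
  ## conflicting evidence yields ? with the conflict flag
  gX <- genotypeSite(c(mkReads(fx$carrier, 1L), mkReads(fx$ref, 2L)),
                     fx$flanks)
  expect_true(is.na(gX$value))
  expect_true(gX$conflict)
})

test_that("the batched PAV builder agrees with per-site genotyping", {
  fx <- panelFixture()
  pav <- panelPavFixture()
  sites <- panelSites(fx$panel)
  fl <- lapply(c(2L, 9L), function(i)
    extractSiteFlanks(simGenome(fx$sim), sites$chrom[i], sites$pos[i],
                      consensusLTR(simConsensus(fx$sim)),
                      tsdLength = 5L, siteId = sites$site_id[i]))
  for (a in rownames(pavValues(pav))[c(1L, 7L)]) {
    for (k in seq_along(fl)) {
      g <- genotypeSite(fx$reads[[a]], fl[[k]])
      expect_identical(pavValues(pav)[a, fl[[k]]$site_id], g$value)
      expect_identical(pavSupport(pav)$present[a, fl[[k]]$site_id],
                       g$supportPresent)
    }
  }
})

test_that("PAV matrix rows are read-order invariant and replicate-consistent", {
  fx <- panelFixture()
  sites <- panelSites(fx$panel)
  fl <- lapply(1:4, function(i)
    extractSiteFlanks(simGenome(fx$sim), sites$chrom[i], sites$pos[i],
                      consensusLTR(simConsensus(fx$sim)),
                      tsdLength = 5L, siteId = sites$site_id[i]))
  acc <- names(fx$reads)[1]
  reads <- fx$reads[[acc]]
  shuffled <- reads[rev(seq_along(reads))]
  ## a duplicated accession read set (the replicate-line case) gives an
  ## identical row; read order does not matter
  pav <- buildPavMatrix(list(a = reads, a_rep = shuffled), fl)
  v <- pavValues(pav)
  expect_identical(unname(v["a", ]), unname(v["a_rep", ]))
  ## a zero-coverage accession is all-missing
  empty <- Biostrings::DNAStringSet()
  pav0 <- buildPavMatrix(list(z = empty), fl)
  expect_true(all(is.na(pavValues(pav0))))
})

test_that("missingness is non-increasing in coverage and calls never flip", {
  fx <- genotypeFixture()
  missRate <- function(coverage) {
    cfg <- trimSimConfig(seed = 131L, chromosomeLengths = 10000L,
                         coverage = coverage, errorRate = 0)
    vals <- vapply(1:6, function(s) {
      reads <- with(simulateReads(fx$carrier, cfg, seed = s), c(r1, r2))
      g <- genotypeSite(reads, fx$flanks)
      ## a non-missing call from an error-free carrier must be 1
      if (!is.na(g$value)) expect_identical(g$value, 1L)
      is.na(g$value)
    }, logical(1))
    mean(vals)
  }
  rates <- vapply(c(0.5, 3, 12), missRate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_identical(rates[3], 0)
})

test_that("detection rate reproduces printed-table arithmetic and tallies", {
  ## 5038 callable of 6156 cells -> 82%
  v <- matrix(1L, 76L, 81L,
              dimnames = list(paste0("a", 1:76), paste0("s", 1:81)))
  v[seq_len(6156L - 5038L)] <- NA_integer_
  dr <- detectionRate(pavMatrix(v))
  expect_equal(dr$called[dr$group == "overall"], 5038L)
  expect_equal(dr$rate_percent[dr$group == "overall"], 82)
  ## no missing cells: 100%
  expect_equal(detectionRate(matrix(0L, 2, 2,
    dimnames = list(c("x", "y"), c("s1", "s2"))))$rate_percent, 100)
  ## constructed missingness pattern matches a direct tally per group
  set.seed(8)
  v2 <- matrix(sample(c(1L, 0L, NA), 60L, TRUE), 6L, 10L,
               dimnames = list(paste0("a", 1:6), paste0("s", 1:10)))
  groups <- setNames(rep(c("g1", "g2"), each = 3L), paste0("a", 1:6))
  dr2 <- detectionRate(v2, groups)
  for (g in c("g1", "g2")) {
    sub <- v2[names(groups)[groups == g], ]
    expect_equal(dr2$called[dr2$group == g], sum(!is.na(sub)))
  }
  expect_error(detectionRate(matrix(integer(), 0, 0)), "empty")
})

test_that("site classification recovers planted sharing classes", {
  fx <- panelFixture()
  geno <- panelGenotypes(fx$panel)
  groups <- panelGroups(fx$panel)
  cls <- classifySitesByGroup(geno, groups)
  truth <- panelSites(fx$panel)
  expected <- c(fixed = "fixed_in_all", group_private = "group_restricted",
                line_private = "line_specific")
  expect_equal(cls$class[match(truth$site_id, cls$site)],
               unname(expected[truth$class]))
  expect_false(any(cls$indeterminate))
  ## carriers spanning several groups are 'shared'
  m <- geno[, 1:2]
  m[, 2] <- c(1L, rep(0L, 10L), 1L)
  colnames(m) <- c("x", "y")
  cls2 <- classifySitesByGroup(m, groups)
  expect_equal(cls2$class[cls2$site == "y"], "shared")
  ## subgroup mapping refines a group-restricted site
  sub <- groups
  sub[groups == "modern"] <- rep(c("tropical", "temperate"), each = 2L)
  m3 <- geno[, 1, drop = FALSE]
  m3[] <- 0L
  m3[which(sub == "tropical"), 1] <- 1L
  cls3 <- classifySitesByGroup(m3, groups, sub)
  expect_equal(cls3$class, "subgroup_specific")
})
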