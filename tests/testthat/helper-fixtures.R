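## Shared fixtures, built once per test session, and independent oracles.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## 100-kb reference with 12 planted elements of mixed category, one 3-LTR
## and one 4-LTR tandem, one nested insertion.
refFixture <- function() fixture("ref", function() {
  cfg <- trimSimConfig(seed = 11L, chromosomeLengths = c(50000L, 50000L))
  sim <- makeReferenceGenome(cfg)
  list(cfg = cfg, sim = sim,
       model = asTrimModel(simConsensus(sim)),
       ann = annotateGenome(simGenome(sim), asTrimModel(simConsensus(sim))))
})

## 12-accession, 3-group panel over a 60-kb reference: 5 fixed +
## 6 group-private + 4 line-private sites, 20x error-free reads.
panelFixture <- function() fixture("panel", function() {
  cfg <- trimSimConfig(seed = 21L,
                       chromosomeLengths = c(20000L, 20000L, 20000L),
                       coverage = 20, errorRate = 0,
                       groupSizes = c(modern = 4L, landrace = 4L,
                                      teosinte = 4L),
                       nFixedSites = 5L, nGroupPrivateSites = 6L,
                       nLinePrivateSites = 4L)
  sim <- makeReferenceGenome(cfg, nIntact = 2L, nSolo = 1L, nTruncated = 0L,
                             extraLtrCounts = integer(), nNested = 0L)
  panel <- buildPopulation(sim, cfg)
  accs <- names(panelGenomes(panel))
  reads <- lapply(accs, function(a) {
    rd <- simulateReads(panelGenomes(panel)[[a]], cfg,
                        seed = childSeedFor(a, accs), idPrefix = a)
    c(rd$r1, rd$r2)
  })
  names(reads) <- accs
  ann <- annotateGenome(simGenome(sim), asTrimModel(simConsensus(sim)))
  list(cfg = cfg, sim = sim, panel = panel, reads = reads, ann = ann)
})

childSeedFor <- function(acc, accs) 1000L + match(acc, accs)

## per-accession insertion calls on the panel fixture (expensive; cached)
panelCallsFixture <- function() fixture("panelCalls", function() {
  fx <- panelFixture()
  cons <- simConsensus(fx$sim)
  calls <- lapply(names(fx$reads), function(a)
    detectInsertions(fx$reads[[a]], consensusLTR(cons), simGenome(fx$sim),
                     fx$ann))
  names(calls) <- names(fx$reads)
  calls
})

## genotyped PAV matrix of the truth sites on the panel fixture (cached)
panelPavFixture <- function() fixture("panelPav", function() {
  fx <- panelFixture()
  sites <- panelSites(fx$panel)
  fl <- lapply(seq_len(nrow(sites)), function(i)
    extractSiteFlanks(simGenome(fx$sim), sites$chrom[i], sites$pos[i],
                      consensusLTR(simConsensus(fx$sim)),
                      tsdLength = 5L, siteId = sites$site_id[i]))
  buildPavMatrix(fx$reads, fl)
})

## ---- independent oracles ----

## K2P distance by direct formula evaluation (independent of kimura2p)
k2pOracle <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

## proportion of transition / transversion differences between two
## equal-length character sequences (independent counting path)
pqOracle <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  pur <- c("A", "G")
  d <- a != b
  ts <- d & ((a %in% pur) == (b %in% pur))
  c(P = mean(ts), Q = mean(d & !ts))
}

## exhaustive least-squares topology search (oracle for NJ on additive
## matrices): returns the topology with minimum LS residual
lsTopologyOracle <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(utils::combn(n, 2L))
  dvec <- d[pairs]
  best <- NULL
  bestRss <- Inf
  for (k in seq_along(trees)) {
    tr <- trees[[k]]      # [[ restores compressed tip labels on multiPhylo
    nTips <- length(tr$tip.label)
    tipSets <- lapply(seq_len(nrow(tr$edge)), function(e) {
      node <- tr$edge[e, 2L]
      if (node <= nTips) node
      else unlist(phangorn::Descendants(tr, node, "tips"))
    })
    ## map oracle tree tip indices back to the label order of d
    tipLab <- tr$tip.label
    A <- vapply(tipSets, function(s) {
      inS <- labs %in% tipLab[s]
      xor(inS[pairs[, 1L]], inS[pairs[, 2L]])
    }, logical(nrow(pairs))) + 0
    co <- qr.coef(qr(A), dvec)
    co[is.na(co)] <- 0          # rank-deficient topologies: any LS solution
    fitted <- A %*% co
    rss <- sum((fitted - dvec)^2)
    if (rss < bestRss - 1e-12) {
      bestRss <- rss
      best <- tr
    }
  }
  best
}

## cophenetic distances of a tree with branch lengths (additive matrix maker)
treeDistances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

randomReads <- function(n, len, seed = 1L) {
  set.seed(seed)
  x <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1)))
  names(x) <- paste0("r", seq_len(n))
  x
}
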