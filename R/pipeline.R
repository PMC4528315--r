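## End-to-end orchestration: each stage reads its inputs from, and writes
## its outputs to, a run directory, so every report number is re-derivable
## from on-disk stage TSVs. Stages are independently invokable.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    chromosome_lengths = c(50000L, 50000L),
    gc_content = 0.46,
    ltr_length = 230L,
    internal_length = 72L,
    tsd_length = 5L,
    substitution_rate = 1.3e-8,
    ts_tv_ratio = 2,
    read_length = 150L,
    insert_size_mean = 400,
    insert_size_sd = 40,
    coverage = 5,
    error_rate = 0.002,
    group_sizes = c(modern = 4L, landrace = 4L, teosinte = 4L),
    n_fixed_sites = 5L,
    n_group_private_sites = 6L,
    n_line_private_sites = 4L,
    n_intact = 6L, n_solo = 3L, n_truncated = 3L,
    min_identity = 0.80,
    min_coverage = 0.80,
    min_ltr_match = 20L,
    min_flank = 20L,
    max_mismatch = 1L,
    cluster_window = 10L,
    flank_size = 150L,
    min_junction_overlap = 20L,
    verbosity = 1L)
}

#' Assemble and validate a pipeline configuration
#'
#' @param file optional YAML file of settings.
#' @param ... individual overrides (applied after the file). Unknown keys
#'   are rejected.
#' @return a validated named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- pipelineDefaults()
  supplied <- list()
  if (!is.null(file)) supplied <- yaml::read_yaml(file)
  supplied <- utils::modifyList(supplied, list(...))
  unknown <- setdiff(names(supplied), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, supplied)
  structure(cfg, class = "pipelineConfig")
}

asSimConfig <- function(cfg) {
  trimSimConfig(seed = cfg$seed,
                chromosomeLengths = cfg$chromosome_lengths,
                gcContent = cfg$gc_content,
                ltrLength = cfg$ltr_length,
                internalLength = cfg$internal_length,
                tsdLength = cfg$tsd_length,
                substitutionRate = cfg$substitution_rate,
                tsTvRatio = cfg$ts_tv_ratio,
                readLength = cfg$read_length,
                insertSizeMean = cfg$insert_size_mean,
                insertSizeSd = cfg$insert_size_sd,
                coverage = cfg$coverage,
                errorRate = cfg$error_rate,
                groupSizes = cfg$group_sizes,
                nFixedSites = cfg$n_fixed_sites,
                nGroupPrivateSites = cfg$n_group_private_sites,
                nLinePrivateSites = cfg$n_line_private_sites)
}

stagePath <- function(outDir, ...) file.path(outDir, ...)

requireStage <- function(path, stage, neededBy) {
  if (!file.exists(path))
    stop("stage '", neededBy, "' requires ", basename(path),
         "; run '", stage, "' first")
  path
}

logMsg <- function(cfg, ...) if (isTRUE(cfg$verbosity >= 1L)) message(...)

writeManifest <- function(outDir, files) {
  sums <- tools::md5sum(files)
  writeTsv(data.frame(file = basename(files), md5 = unname(sums)),
           stagePath(outDir, "manifest.tsv"))
}

#' Simulate a reference, panel, and reads into a run directory
#'
#' Writes the reference FASTA, consensus FASTA, truth GFF3/TSVs,
#' per-accession paired FASTQ, the effective configuration, and a checksum
#' manifest.
#'
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory (created if missing).
#' @return invisible list of written paths.
#' @export
runSimulate <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sc <- asSimConfig(config)
  sim <- makeReferenceGenome(sc, nIntact = config$n_intact,
                             nSolo = config$n_solo,
                             nTruncated = config$n_truncated)
  panel <- buildPopulation(sim, sc)
  files <- character()
  files <- c(files, writeGenomeFasta(simGenome(sim),
                                     stagePath(outDir, "reference.fasta")))
  cons <- simConsensus(sim)
  consSet <- Biostrings::DNAStringSet(list(
    ltr = consensusLTR(cons),
    internal = consensusInternal(cons),
    element = consensusSequence(cons)))
  files <- c(files, writeGenomeFasta(consSet,
                                     stagePath(outDir, "consensus.fasta")))
  files <- c(files, writeElementsGff3(simElements(sim),
                                      stagePath(outDir, "truth_elements.gff3")))
  files <- c(files, writeTsv(panelSites(panel),
                             stagePath(outDir, "truth_sites.tsv")))
  geno <- panelGenotypes(panel)
  files <- c(files, writeTsv(
    data.frame(accession = rownames(geno), geno, check.names = FALSE),
    stagePath(outDir, "truth_genotypes.tsv")))
  files <- c(files, writeTsv(
    data.frame(accession = names(panelGroups(panel)),
               group = unname(panelGroups(panel))),
    stagePath(outDir, "groups.tsv")))
  readsDir <- stagePath(outDir, "reads")
  dir.create(readsDir, showWarnings = FALSE)
  origins <- list()
  for (acc in names(panelGenomes(panel))) {
    rd <- simulateReads(panelGenomes(panel)[[acc]], sc,
                        seed = childSeed(sc@seed, match(
                          acc, names(panelGenomes(panel))) + 10L),
                        idPrefix = acc)
    files <- c(files, writeReadsFastq(rd, file.path(readsDir, acc)))
    org <- rd$origins
    if (nrow(org)) org$accession <- acc
    origins[[acc]] <- org
  }
  files <- c(files, writeTsv(do.call(rbind, origins),
                             stagePath(outDir, "truth_read_origins.tsv")))
  yaml::write_yaml(unclass(config), stagePath(outDir, "config.yaml"))
  files <- c(files, stagePath(outDir, "config.yaml"))
  writeManifest(outDir, files)
  logMsg(config, "simulate: ", length(panelGenomes(panel)), " accessions, ",
         length(simElements(sim)), " reference elements, ",
         nrow(panelSites(panel)), " panel sites")
  invisible(list(dir = outDir, files = files))
}

#' Annotate the simulated (or supplied) reference genome
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory containing \code{reference.fasta} and
#'   \code{consensus.fasta}.
#' @export
runAnnotate <- function(config, outDir) {
  ref <- readGenomeFasta(requireStage(stagePath(outDir, "reference.fasta"),
                                      "simulate", "annotate"))
  cons <- readGenomeFasta(requireStage(stagePath(outDir, "consensus.fasta"),
                                       "simulate", "annotate"))
  model <- trimModel(cons[["ltr"]], cons[["internal"]],
                     tsdLength = config$tsd_length,
                     minIdentity = config$min_identity,
                     minCoverage = config$min_coverage)
  ann <- annotateGenome(ref, model)
  writeElementsGff3(ann, stagePath(outDir, "elements.gff3"))
  dens <- chromosomeDensity(ann, setNames(Biostrings::width(ref) / 1e6,
                                          names(ref)))
  writeTsv(dens, stagePath(outDir, "chromosome_density.tsv"))
  logMsg(config, "annotate: ", length(ann), " elements (",
         paste(names(table(ann$category)), table(ann$category),
               sep = "=", collapse = ", "), ")")
  invisible(ann)
}

#' Date intact elements from LTR divergence
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory containing \code{elements.gff3}.
#' @export
runDate <- function(config, outDir) {
  ref <- readGenomeFasta(requireStage(stagePath(outDir, "reference.fasta"),
                                      "simulate", "date"))
  ann <- readElementsGff3(requireStage(stagePath(outDir, "elements.gff3"),
                                       "annotate", "date"))
  est <- dateElements(ref, ann, r = config$substitution_rate)
  writeTsv(est, stagePath(outDir, "dating.tsv"))
  if (nrow(est)) {
    writeTsv(ageHistogram(est), stagePath(outDir, "age_histogram.tsv"))
  } else {
    warning("no intact elements to date; empty dating table written")
  }
  logMsg(config, "date: ", nrow(est), " elements dated, ",
         length(attr(est, "excluded")), " excluded")
  invisible(est)
}

panelReadSets <- function(outDir) {
  readsDir <- stagePath(outDir, "reads")
  f1 <- sort(list.files(readsDir, pattern = "_1\\.fastq$",
                        full.names = TRUE))
  if (!length(f1)) stop("no FASTQ files under ", readsDir,
                        "; run 'simulate' first")
  accs <- sub("_1\\.fastq$", "", basename(f1))
  sets <- lapply(seq_along(f1), function(i)
    c(readFastq(f1[i]), readFastq(sub("_1\\.fastq$", "_2.fastq", f1[i]))))
  names(sets) <- accs
  sets
}

#' Detect non-reference insertions in every accession
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory with reads and annotation.
#' @export
runDetect <- function(config, outDir) {
  ref <- readGenomeFasta(requireStage(stagePath(outDir, "reference.fasta"),
                                      "simulate", "detect"))
  cons <- readGenomeFasta(requireStage(stagePath(outDir, "consensus.fasta"),
                                       "simulate", "detect"))
  ann <- readElementsGff3(requireStage(stagePath(outDir, "elements.gff3"),
                                       "annotate", "detect"))
  sets <- panelReadSets(outDir)
  calls <- lapply(names(sets), function(acc) {
    cl <- detectInsertions(sets[[acc]], cons[["ltr"]], ref, ann,
                           minLtrMatch = config$min_ltr_match,
                           minFlank = config$min_flank,
                           maxMismatch = config$max_mismatch,
                           clusterWindow = config$cluster_window)
    if (nrow(cl)) cl$accession <- acc
    cl
  })
  names(calls) <- names(sets)
  combined <- do.call(rbind, calls[vapply(calls, nrow, 1L) > 0])
  writeTsv(combined, stagePath(outDir, "insertion_calls.tsv"))
  nonref <- lapply(calls, function(cl)
    cl[cl$status == "non_reference", , drop = FALSE])
  nonref <- nonref[vapply(nonref, nrow, 1L) > 0]
  if (length(nonref)) {
    sh <- sharingSummary(nonref, clusterWindow = config$cluster_window)
    writeTsv(sh, stagePath(outDir, "sharing_summary.tsv"))
  }
  logMsg(config, "detect: ", sum(combined$status == "non_reference"),
         " non-reference calls across ", length(sets), " accessions")
  invisible(calls)
}

## distinct non-reference sites across accessions (clustered)
distinctNonrefSites <- function(callsTable, clusterWindow) {
  nr <- callsTable[callsTable$status == "non_reference", , drop = FALSE]
  if (!nrow(nr)) return(nr[0, c("chrom", "pos", "tsd")])
  out <- list()
  for (ch in unique(nr$chrom)) {
    sub <- nr[nr$chrom == ch, , drop = FALSE]
    ids <- clusterPositions(sub$pos, clusterWindow)
    for (cc in unique(ids)) {
      grp <- sub[ids == cc, , drop = FALSE]
      tsd <- grp$tsd[!is.na(grp$tsd)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = as.integer(round(stats::median(grp$pos))),
        tsd = if (length(tsd)) tsd[1L] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genotype all known sites in all accessions
#'
#' Known sites are the distinct detected non-reference insertions plus the
#' annotated reference elements.
#'
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory with detection output.
#' @export
runGenotype <- function(config, outDir) {
  ref <- readGenomeFasta(requireStage(stagePath(outDir, "reference.fasta"),
                                      "simulate", "genotype"))
  cons <- readGenomeFasta(requireStage(stagePath(outDir, "consensus.fasta"),
                                       "simulate", "genotype"))
  ann <- readElementsGff3(requireStage(stagePath(outDir, "elements.gff3"),
                                       "annotate", "genotype"))
  callsTable <- readTsv(requireStage(stagePath(outDir, "insertion_calls.tsv"),
                                     "detect", "genotype"))
  sites <- distinctNonrefSites(callsTable, config$cluster_window)
  flanksList <- list()
  for (i in seq_len(nrow(sites))) {
    flanksList[[length(flanksList) + 1L]] <- extractSiteFlanks(
      ref, sites$chrom[i], sites$pos[i], cons[["ltr"]],
      flank = config$flank_size, tsdLength = config$tsd_length,
      siteId = sprintf("NR_%s_%d", sites$chrom[i], sites$pos[i]))
  }
  for (i in seq_along(ann)) {
    flanksList[[length(flanksList) + 1L]] <- extractSiteFlanks(
      ref, ltr = cons[["ltr"]], flank = config$flank_size,
      tsdLength = config$tsd_length, element = ann[i],
      siteId = paste0("REF_", ann[i]$element_id))
  }
  sets <- panelReadSets(outDir)
  pav <- buildPavMatrix(sets, flanksList,
                        minJunctionOverlap = config$min_junction_overlap,
                        mismatchPer20 = config$max_mismatch)
  writePavTsv(pav, stagePath(outDir, "pav_matrix.tsv"))
  groupsFile <- stagePath(outDir, "groups.tsv")
  groups <- NULL
  if (file.exists(groupsFile)) {
    gdf <- readTsv(groupsFile)
    groups <- setNames(gdf$group, gdf$accession)
  }
  writeTsv(detectionRate(pav, groups),
           stagePath(outDir, "detection_rate.tsv"))
  if (!is.null(groups))
    writeTsv(classifySitesByGroup(pav, groups),
             stagePath(outDir, "site_classes.tsv"))
  logMsg(config, "genotype: ", nrow(pavValues(pav)), " accessions x ",
         ncol(pavValues(pav)), " sites; missing rate ",
         round(100 * mean(is.na(pavValues(pav))), 1), "%")
  invisible(pav)
}

#' Infer the accession tree from the PAV matrix
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory with \code{pav_matrix.tsv}.
#' @export
runTree <- function(config, outDir) {
  pav <- readPavTsv(requireStage(stagePath(outDir, "pav_matrix.tsv"),
                                 "genotype", "tree"))
  ## monomorphic and all-missing sites carry no signal
  v <- pavValues(pav)
  keep <- apply(v, 2, function(col) length(unique(col[!is.na(col)])) > 1L)
  if (any(keep)) v <- v[, keep, drop = FALSE]
  md <- meanPairwiseDistance(v)
  writeDistanceTsv(md$d, stagePath(outDir, "distances.tsv"))
  tree <- neighborJoining(md$d)
  writeLines(toNewick(tree), stagePath(outDir, "tree.nwk"))
  logMsg(config, "tree: ", length(tree$tip.label), " tips written")
  invisible(tree)
}

#' Summarize a completed run from its stage outputs
#'
#' Every reported figure is recomputed from the on-disk stage TSVs — no
#' hidden state.
#'
#' @param outDir run directory.
#' @return a list of summary tables, written to \code{report.txt}.
#' @export
summarizeRun <- function(outDir) {
  rep <- list()
  annFile <- stagePath(outDir, "elements.gff3")
  if (file.exists(annFile)) {
    ann <- readElementsGff3(annFile)
    rep$category_counts <- as.data.frame(table(category = ann$category))
  }
  for (nm in c("chromosome_density", "age_histogram", "sharing_summary",
               "detection_rate", "site_classes")) {
    f <- stagePath(outDir, paste0(nm, ".tsv"))
    if (file.exists(f)) rep[[nm]] <- readTsv(f)
  }
  treeFile <- stagePath(outDir, "tree.nwk")
  if (file.exists(treeFile)) rep$tree <- readLines(treeFile)
  con <- file(stagePath(outDir, "report.txt"), "w")
  on.exit(close(con))
  for (nm in names(rep)) {
    writeLines(paste0("## ", nm), con)
    if (is.data.frame(rep[[nm]]))
      utils::write.table(rep[[nm]], con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else writeLines(rep[[nm]], con)
    writeLines("", con)
  }
  invisible(rep)
}

#' Run the whole pipeline
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outDir run directory.
#' @return invisible list of stage results.
#' @export
runAll <- function(config, outDir) {
  runSimulate(config, outDir)
  ann <- runAnnotate(config, outDir)
  est <- runDate(config, outDir)
  calls <- runDetect(config, outDir)
  pav <- runGenotype(config, outDir)
  tree <- runTree(config, outDir)
  report <- summarizeRun(outDir)
  invisible(list(annotation = ann, dating = est, calls = calls,
                 pav = pav, tree = tree, report = report))
}
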