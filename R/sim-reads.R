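## Paired-end read simulation with per-read ground-truth origins.

## Apply uniform substitution errors at `rate` to a DNAStringSet.
applySequencingErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  widths <- Biostrings::width(reads)
  nErr <- rbinom(length(reads), widths, rate)
  hit <- which(nErr > 0L)
  if (!length(hit)) return(reads)
  chars <- strsplit(as.character(reads[hit]), "")
  for (k in seq_along(hit)) {
    i <- hit[k]
    posns <- sample.int(widths[i], nErr[i])
    for (p in posns) {
      cur <- chars[[k]][p]
      chars[[k]][p] <- sample(setdiff(DNA_BASES4, cur), 1L)
    }
  }
  reads[hit] <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  reads
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along each chromosome (fragment count per
#' chromosome is Poisson with mean coverage * length / (2 * readLength)),
#' fragment sizes are normal, mate 2 is the reverse complement of the
#' fragment's 3' end, and sequencing errors are uniform substitutions.
#' Every read's source interval and strand is logged.
#'
#' @param genome a \code{DNAStringSet}.
#' @param config a \code{\linkS4class{TrimSimConfig}} supplying
#'   \code{readLength}, \code{insertSizeMean}, \code{insertSizeSd},
#'   \code{coverage}, and \code{errorRate}.
#' @param seed RNG seed (defaults to the config seed).
#' @param idPrefix prefix for read identifiers (useful when simulating many
#'   accessions).
#' @return a list: \code{r1}, \code{r2} (named \code{DNAStringSet}s) and
#'   \code{origins}, a data.frame with \code{read_id}, \code{mate},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (1-based
#'   source intervals).
#' @export
simulateReads <- function(genome, config, seed = config@seed,
                          idPrefix = "read") {
  stopifnot(is(genome, "DNAStringSet"))
  rl <- config@readLength
  if (rl > config@insertSizeMean)
    stop("readLength must not exceed insertSizeMean")
  withSeed(childSeed(seed, 4L), {
    r1 <- list(); r2 <- list(); org <- list()
    counter <- 0L
    for (ch in names(genome)) {
      len <- Biostrings::width(genome)[match(ch, names(genome))]
      lambda <- config@coverage * len / (2 * rl)
      n <- if (lambda > 0) rpois(1L, lambda) else 0L
      if (n == 0L) next
      fragLen <- pmin(pmax(round(rnorm(n, config@insertSizeMean,
                                       config@insertSizeSd)), rl), len)
      start <- floor(runif(n) * (len - fragLen + 1)) + 1L
      frag <- Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(start, width = fragLen))
      m1 <- Biostrings::subseq(frag, 1L, rl)
      m2 <- Biostrings::reverseComplement(
        Biostrings::subseq(frag, fragLen - rl + 1L, fragLen))
      ids <- paste0(idPrefix, ":", ch, ":", counter + seq_len(n))
      counter <- counter + n
      names(m1) <- names(m2) <- ids
      r1[[ch]] <- m1
      r2[[ch]] <- m2
      org[[ch]] <- data.frame(
        read_id = rep(ids, 2L),
        mate = rep(1:2, each = n),
        chrom = ch,
        start = c(start, start + fragLen - rl),
        end = c(start + rl - 1L, start + fragLen - 1L),
        strand = rep(c("+", "-"), each = n),
        stringsAsFactors = FALSE)
    }
    if (!length(r1)) {
      empty <- Biostrings::DNAStringSet()
      return(list(r1 = empty, r2 = empty,
                  origins = data.frame(read_id = character(),
                                       mate = integer(), chrom = character(),
                                       start = integer(), end = integer(),
                                       strand = character())))
    }
    r1 <- do.call(c, unname(r1))
    r2 <- do.call(c, unname(r2))
    list(r1 = applySequencingErrors(r1, config@errorRate),
         r2 = applySequencingErrors(r2, config@errorRate),
         origins = do.call(rbind, unname(org)))
  })
}

#' Write paired reads as FASTQ
#'
#' @param reads a list with \code{r1} and \code{r2} as returned by
#'   \code{\link{simulateReads}}.
#' @param prefix output path prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq} with /1 and /2 read-name suffixes.
#' @return the two file paths, invisibly.
#' @export
writeReadsFastq <- function(reads, prefix) {
  files <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    x <- reads[[paste0("r", m)]]
    names(x) <- paste0(names(x), "/", m)
    Biostrings::writeXStringSet(
      x, files[m], format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
  }
  invisible(files)
}

#' Read a FASTQ file as a DNAStringSet
#' @param path FASTQ file path.
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
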