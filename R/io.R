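## Readers and writers for the pipeline's on-disk formats: FASTA genomes,
## GFF3 element annotations, TSV tables, and the PAV matrix.

#' Write a genome (or any sequence set) as FASTA
#' @param seqs a \code{DNAStringSet}.
#' @param path output file.
#' @export
writeGenomeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#' @param path FASTA file; names are truncated at the first whitespace.
#' @export
readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write annotated elements as GFF3
#'
#' Elements become \code{mobile_genetic_element} features; category, LTR
#' count, TSD, LTR sub-intervals, and nested insertions travel as
#' attributes.
#'
#' @param elements a \code{GRanges} from \code{\link{annotateGenome}} (or a
#'   simulation truth ledger).
#' @param path output file.
#' @export
writeElementsGff3 <- function(elements, path) {
  gr <- elements
  if (length(gr)) {
    gr$type <- "mobile_genetic_element"
    gr$ID <- gr$element_id
  }
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read elements back from GFF3
#' @param path GFF3 file written by \code{\link{writeElementsGff3}}.
#' @return a \code{GRanges} with integer \code{ltr_count} restored.
#' @export
readElementsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(gr$ltr_count)) gr$ltr_count <- as.integer(gr$ltr_count)
  if (!is.null(gr$age_years)) gr$age_years <- as.numeric(gr$age_years)
  if (!is.null(gr$insertion_point))
    gr$insertion_point <- as.integer(gr$insertion_point)
  gr
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a PAV matrix as TSV
#'
#' Cells are "1"/"0"/"?", the header row holds site ids, and the first
#' column holds accession ids.
#'
#' @param pav a \code{\linkS4class{PAVMatrix}}.
#' @param path output file.
#' @export
writePavTsv <- function(pav, path) {
  ch <- pavCharacters(pav)
  df <- data.frame(accession = rownames(ch), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' Read a PAV matrix from TSV
#' @param path file written by \code{\link{writePavTsv}}.
#' @return a \code{\linkS4class{PAVMatrix}} (support counts zeroed).
#' @export
readPavTsv <- function(path) {
  df <- readTsv(path, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  pavMatrix(m)
}

#' Write a distance matrix as TSV
#' @param d symmetric labelled matrix.
#' @param path output file.
#' @export
writeDistanceTsv <- function(d, path) {
  df <- data.frame(accession = rownames(d), d, check.names = FALSE)
  writeTsv(df, path)
}
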