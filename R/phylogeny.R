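## Distance and tree inference from the presence/absence matrix: the mean
## pairwise character difference with pairwise deletion of missing cells,
## and Saitou-Nei neighbor joining.

#' Mean pairwise character difference with missing-data adjustment
#'
#' d(i, j) = (# sites where both accessions are scored and differ) /
#' (# sites where both are scored). With no missing data this reduces to the
#' plain Hamming proportion. \code{listwise = TRUE} instead drops every site
#' with any missing cell before computing plain Hamming distances.
#'
#' @param pav a \code{\linkS4class{PAVMatrix}} or integer matrix (NA =
#'   missing).
#' @param listwise use listwise instead of pairwise deletion.
#' @return list: \code{d} (symmetric distance matrix, zero diagonal) and
#'   \code{overlap} (per-pair count of jointly scored sites).
#' @examples
#' m <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 0L))
#' colnames(m) <- paste0("s", 1:3)
#' meanPairwiseDistance(m)$d["a", "b"]  # 1/3
#' @export
meanPairwiseDistance <- function(pav, listwise = FALSE) {
  v <- if (is(pav, "PAVMatrix")) pavValues(pav) else pav
  if (is.null(rownames(v))) rownames(v) <- paste0("acc", seq_len(nrow(v)))
  if (nrow(v) < 2L) stop("need at least two accessions")
  if (listwise) v <- v[, colSums(is.na(v)) == 0L, drop = FALSE]
  n <- nrow(v)
  labs <- rownames(v)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  ov <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(v[i, ]) & !is.na(v[j, ])
    m <- sum(ok)
    if (m == 0L)
      stop("accessions ", labs[i], " and ", labs[j],
           " share no scored sites; distance undefined")
    dij <- sum(v[i, ok] != v[j, ok]) / m
    d[i, j] <- d[j, i] <- dij
    ov[i, j] <- ov[j, i] <- m
  }
  diag(ov) <- as.integer(rowSums(!is.na(v)))
  list(d = d, overlap = ov)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration under the standard Q criterion. Ties are broken
#' by the smallest label-index pair. A negative branch length is clamped to
#' zero with the deficit transferred to its sibling branch, so each joined
#' pair keeps its summed length.
#'
#' @param d symmetric distance matrix with labelled rows/columns (or the
#'   list returned by \code{\link{meanPairwiseDistance}}).
#' @return an unrooted \code{phylo} tree (ape). Two taxa give a single edge
#'   reported as two half-length branches.
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A","B"), c("A","B")))
#' toNewick(neighborJoining(d))
#' @export
neighborJoining <- function(d) {
  if (is.list(d) && !is.matrix(d)) d <- d$d
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2L) stop("need at least two taxa")
  node <- as.list(quoteNewickLabel(labs))  # newick fragment per active node
  D <- d
  clamp <- function(b1, b2) {
    if (b1 < 0) { b2 <- b2 + b1; b1 <- 0 }
    if (b2 < 0) { b1 <- b1 + b2; b2 <- 0 }
    c(max(b1, 0), max(b2, 0))
  }
  fmt <- function(x) sprintf("%.6g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ## smallest Q; ties -> smallest (i, j) in current index order
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    b <- clamp(bi, bj)
    newFrag <- paste0("(", node[[i]], ":", fmt(b[1]), ",",
                      node[[j]], ":", fmt(b[2]), ")")
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
                c(newD[keep], 0))
    node <- c(node[keep], newFrag)
    D <- D2
  }
  if (nrow(D) == 2L) {
    half <- D[1, 2] / 2
    nwk <- paste0("(", node[[1]], ":", fmt(half), ",",
                  node[[2]], ":", fmt(half), ");")
  } else {
    b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    x <- clamp(b1, b2); b1 <- x[1]; b2 <- x[2]
    if (b3 < 0) b3 <- 0
    nwk <- paste0("(", node[[1]], ":", fmt(b1), ",", node[[2]], ":",
                  fmt(b2), ",", node[[3]], ":", fmt(b3), ");")
  }
  readNewick(text = nwk)
}

needsQuoting <- function(lab) grepl("[][ ():;,']", lab)

quoteNewickLabel <- function(lab) {
  ifelse(needsQuoting(lab), paste0("'", gsub("'", "''", lab), "'"), lab)
}

#' Serialize a tree as Newick
#'
#' Branch lengths are written with 6 significant digits; labels containing
#' spaces or Newick metacharacters are single-quoted. Round-trips through
#' \code{\link{readNewick}}.
#'
#' @param tree a \code{phylo} object.
#' @return a single Newick string, terminated with ";".
#' @export
toNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  fmt <- function(x) sprintf("%.6g", x)
  quote_ <- quoteNewickLabel
  nTips <- length(tree$tip.label)
  root <- nTips + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(nodeIdx, edgeIdx) {
    lab <- if (nodeIdx <= nTips) quote_(tree$tip.label[nodeIdx])
    else {
      ch <- kids[[as.character(nodeIdx)]]
      paste0("(", paste(vapply(ch, function(eI)
        rec(tree$edge[eI, 2], eI), character(1)), collapse = ","), ")")
    }
    if (is.na(edgeIdx) || is.null(tree$edge.length)) lab
    else paste0(lab, ":", fmt(tree$edge.length[edgeIdx]))
  }
  paste0(rec(root, NA), ";")
}

#' Parse a Newick tree
#'
#' @param file path to a Newick file, or
#' @param text a Newick string.
#' @return a \code{phylo} object.
#' @export
readNewick <- function(file = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(file)
  ## ape keeps the surrounding quotes of quoted labels; strip and unescape
  quoted <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[quoted] <- gsub(
    "''", "'", sub("^'(.*)'$", "\\1", tree$tip.label[quoted]))
  tree
}

#' Tree from a PAV matrix in one call
#'
#' @param pav a \code{\linkS4class{PAVMatrix}} or integer matrix.
#' @param listwise passed to \code{\link{meanPairwiseDistance}}.
#' @return a \code{phylo} tree.
#' @export
pavTree <- function(pav, listwise = FALSE) {
  neighborJoining(meanPairwiseDistance(pav, listwise = listwise)$d)
}

#' Is a set of tips monophyletic in an unrooted tree?
#'
#' TRUE when some edge bipartition separates exactly the given tips — the
#' unrooted notion of monophyly used to compare tree clusters with known
#' germplasm groups.
#'
#' @param tree a \code{phylo} object.
#' @param tips character vector of tip labels.
#' @export
isGroupMonophyletic <- function(tree, tips) {
  tips <- intersect(tips, tree$tip.label)
  if (length(tips) < 1L) stop("no matching tips")
  if (length(tips) %in% c(1L, length(tree$tip.label))) return(TRUE)
  others <- setdiff(tree$tip.label, tips)
  rooted <- ape::root(tree, outgroup = others[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}
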