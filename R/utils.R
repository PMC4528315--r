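## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

## Round half away from zero (the printed-table convention), unlike base round()
## which rounds half to even.
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream-specific child seed from a base seed; kept well inside
## 32-bit integer range.
childSeed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147480009L
}

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

isCount <- function(x, zero_ok = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) &&
    (x > 0 || (zero_ok && x == 0))
}

DNA_BASES4 <- c("A", "C", "G", "T")

sortByStart <- function(x) x[order(IRanges::start(x))]
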