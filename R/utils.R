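## Internal sequence and alignment helpers.

BASES <- c("A", "C", "G", "T")

## reverse complement of a plain character string (gaps preserved)
revcompChr <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1), USE.NAMES = FALSE))
}

## split a string into a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## random sequence with given GC content
randomSeq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

## default BLASTn-like scoring used throughout the search engine
searchScoring <- function() list(match = 2, mismatch = -3, gapOpen = 5, gapExtend = 2)

## score a gapped alignment (two equal-length strings) under searchScoring()
scoreAlignment <- function(alnQ, alnT, sc = searchScoring()) {
  q <- chars(alnQ); t <- chars(alnT)
  stopifnot(length(q) == length(t))
  gq <- q == "-"; gt <- t == "-"
  if (any(gq & gt)) stop("alignment has a double-gap column")
  m <- sum(!gq & !gt & q == t)
  mm <- sum(!gq & !gt & q != t)
  gaps <- gq | gt
  nOpen <- if (any(gaps)) sum(diff(c(FALSE, gaps)) == 1) else 0
  m * sc$match + mm * sc$mismatch - nOpen * sc$gapOpen - sum(gaps) * sc$gapExtend
}

## identity over aligned non-gap columns
alignmentPid <- function(alnQ, alnT) {
  q <- chars(alnQ); t <- chars(alnT)
  keep <- q != "-" & t != "-"
  if (!sum(keep)) return(0)
  sum(q[keep] == t[keep]) / sum(keep)
}

## Karlin-Altschul ungapped lambda for match/mismatch scoring at uniform base
## composition; solved once per scoring scheme.  K fixed at 0.41 (documented
## constant; E-values are used for thresholding only).
kaLambda <- local({
  cache <- new.env(parent = emptyenv())
  function(match = 2, mismatch = -3) {
    key <- paste(match, mismatch)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
    l <- stats::uniroot(f, c(1e-6, 5))$root
    cache[[key]] <- l
    l
  }
})

approxEvalue <- function(score, qlen, dblen, match = 2, mismatch = -3, K = 0.41) {
  K * qlen * dblen * exp(-kaLambda(match, mismatch) * score)
}

## per-column target positions of a hit alignment.  Returns an integer vector
## (length = alignment columns); gap columns in the target row carry the
## position of the previous aligned base.  Positions ascend for "+" hits and
## descend for "-" hits (whose aln rows are stored in consensus orientation).
alignmentTargetPos <- function(alnT, tstart, tend, strandChar) {
  t <- chars(alnT)
  n <- cumsum(t != "-")
  if (strandChar == "-") tend - n + 1 else tstart + n - 1
}

## per-column query (consensus) positions, always ascending
alignmentQueryPos <- function(alnQ, qstart) {
  q <- chars(alnQ)
  qstart + cumsum(q != "-") - 1
}

## substitution matrix shared by all pairwiseAlignment calls
.tecurSubMat <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE)
    m
  }
})

## classed condition for elements that cannot be curated
uncuratable <- function(name, reason) {
  stop(structure(class = c("tecur_uncuratable", "error", "condition"),
                 list(message = sprintf("'%s' uncuratable: %s", name, reason),
                      call = NULL, name = name, reason = reason)))
}

isUncuratable <- function(e) inherits(e, "tecur_uncuratable")

## seed arithmetic: derive a distinct, 32-bit-safe stream seed
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
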