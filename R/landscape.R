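## Kimura 2-parameter divergence with CpG down-weighting, repeat landscape
## tables, genome summary tables and masking overlap statistics.

#' Kimura 2-parameter distance with CpG down-weighting
#'
#' Computes `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` from a pairwise
#' alignment of a copy against its consensus. Columns containing a gap or N
#' in either row are excluded. P is the transition fraction and Q the
#' transversion fraction over the counted columns; transitions at columns
#' where the consensus row carries a CpG dinucleotide (both positions of
#' the dinucleotide, read along the consensus row skipping gaps) contribute
#' `cpgWeight` instead of 1 — hypermutable CpG transitions are
#' down-weighted rather than excluded. With `cpgWeight = 1` this is the
#' textbook K2P estimator. A non-positive logarithm argument (saturation)
#' returns the sentinel 0.5 with attribute `saturated = TRUE`.
#'
#' @param consensusRow,copyRow equal-length gapped alignment rows
#'   (consensus first).
#' @param cpgWeight weight of a transition at a consensus CpG site.
#' @return the distance (substitutions/site); attribute `saturated`.
#' @export
kimura2p <- function(consensusRow, copyRow, cpgWeight = 0.1) {
  q <- chars(toupper(as.character(consensusRow)))
  t <- chars(toupper(as.character(copyRow)))
  if (length(q) != length(t)) stop("alignment rows differ in length")
  ## CpG mask on the consensus row: C followed by G among non-gap positions
  nonGap <- which(q %in% BASES)
  cpg <- rep(FALSE, length(q))
  if (length(nonGap) > 1) {
    b <- q[nonGap]
    i <- which(b[-length(b)] == "C" & b[-1] == "G")
    cpg[nonGap[i]] <- TRUE
    cpg[nonGap[i + 1]] <- TRUE
  }
  count <- q %in% BASES & t %in% BASES
  N <- sum(count)
  if (!N) stop("no countable columns")
  mism <- count & q != t
  transition <- mism & ((q == "A" & t == "G") | (q == "G" & t == "A") |
                          (q == "C" & t == "T") | (q == "T" & t == "C"))
  transversion <- mism & !transition
  P <- (sum(transition & !cpg) + cpgWeight * sum(transition & cpg)) / N
  Q <- sum(transversion) / N
  arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
  if (!is.finite(arg) || arg <= 0)
    return(structure(0.5, saturated = TRUE))
  structure(-0.5 * log(arg), saturated = FALSE)
}

#' Divergence landscape table from a mask track
#'
#' Assigns each hit's masked bp to the 1-percentage-point bin of its K2P
#' distance (computed with [kimura2p()] from the stored hit alignment
#' against its consensus), stacked per TE class. Distances at or above 50%
#' (including the saturation sentinel) fall into the last bin.
#'
#' @param track a [MaskTrack-class] (hits carry alignments).
#' @param genomeLength genome size for the fraction column (defaults to the
#'   track's).
#' @param cpgWeight passed to [kimura2p()].
#' @param binWidth bin width in percentage points.
#' @return data.frame: `bin` (lower edge, percent), `class`, `bp`,
#'   `fraction` (bp / genome length). All (bin, class) combinations with
#'   nonzero bp, plus zero rows for empty tracks.
#' @export
landscapeTable <- function(track, genomeLength = NULL, cpgWeight = 0.1,
                           binWidth = 1) {
  if (is.null(genomeLength)) genomeLength <- track@genomeLength
  h <- maskHits(track)
  bins <- seq(0, 50 - binWidth, by = binWidth)
  if (!length(h)) {
    return(data.frame(bin = bins, class = "none", bp = 0, fraction = 0))
  }
  m <- mcols(h)
  div <- vapply(seq_along(h), function(i)
    as.numeric(kimura2p(m$aln_q[i], m$aln_t[i], cpgWeight = cpgWeight)),
    numeric(1))
  bi <- pmin(floor(div * 100 / binWidth) * binWidth, 50 - binWidth)
  cls <- hitClass(track)
  df <- data.frame(bin = bi, class = cls, bp = IRanges::width(h))
  agg <- stats::aggregate(bp ~ bin + class, data = df, FUN = sum)
  agg$fraction <- agg$bp / genomeLength
  agg[order(agg$class, agg$bin), , drop = FALSE]
}

#' Genome repeat summary table
#'
#' Per-class copy number, total bp and genome percentage, in the standard
#' annotation-summary layout: rows SINE, LINE, LTR, DNA, Unclassified and a
#' "Total interspersed repeats" row. Percentages are bp / genome length *
#' 100, rounded to 2 decimals.
#'
#' @param track a [MaskTrack-class].
#' @param genomeLength genome size (defaults to the track's).
#' @return data.frame: `type`, `copies`, `bp`, `pct`.
#' @export
summaryTable <- function(track, genomeLength = NULL) {
  if (is.null(genomeLength)) genomeLength <- track@genomeLength
  cls <- hitClass(track)
  cls[cls == "LINE/CR1"] <- "LINE"
  cls[!cls %in% c("SINE", "LINE", "LTR", "DNA")] <- "Unclassified"
  h <- maskHits(track)
  w <- if (length(h)) IRanges::width(h) else integer(0)
  rows <- c("SINE", "LINE", "LTR", "DNA", "Unclassified")
  copies <- vapply(rows, function(r) sum(cls == r), integer(1))
  bp <- vapply(rows, function(r) sum(w[cls == r]), numeric(1))
  out <- data.frame(type = c(rows, "Total interspersed repeats"),
                    copies = c(copies, sum(copies)),
                    bp = c(bp, sum(bp)),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$bp / genomeLength, 2)
  out
}

#' Per-chromosome element density
#'
#' Copies per Mb per sequence for one TE class (used for multi-sequence
#' genomes).
#'
#' @param track a [MaskTrack-class].
#' @param class TE class to count (default "LTR").
#' @return data.frame: `seqname`, `copies`, `mb`, `perMb`.
#' @export
perChromosomeDensity <- function(track, class = "LTR") {
  cls <- hitClass(track)
  h <- maskHits(track)[cls == class]
  sl <- track@seqLengths
  cnt <- table(factor(as.character(seqnames(h)), names(sl)))
  data.frame(seqname = names(sl), copies = as.integer(cnt),
             mb = unname(sl) / 1e6,
             perMb = as.integer(cnt) / (unname(sl) / 1e6),
             stringsAsFactors = FALSE)
}

#' Overlap ratio between a test hit set and a baseline track
#'
#' A test hit overlaps when it shares at least 1 bp with any baseline hit
#' (strand-agnostic, BEDTools-intersect default semantics); the ratio is
#' overlapping test hits / total test hits.
#'
#' @param baseline a [MaskTrack-class] (or GRanges).
#' @param testHits GRanges of test hits (non-empty).
#' @return list: `copies`, `overlaps`, `ratio`.
#' @export
overlapRatio <- function(baseline, testHits) {
  if (is(baseline, "MaskTrack")) baseline <- maskHits(baseline)
  if (!length(testHits)) stop("empty test set")
  ov <- IRanges::overlapsAny(testHits, baseline, ignore.strand = TRUE)
  list(copies = length(testHits), overlaps = sum(ov),
       ratio = sum(ov) / length(testHits))
}
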