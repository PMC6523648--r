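## ERV copy-structure analysis: pseudo full-length consensus, genome-wide
## coverage profiling, solo-LTR vs full-length classification, ORF finding.

#' Concatenate LTR + internal + LTR into a pseudo full-length ERV consensus
#'
#' @param ltr LTR consensus (character/DNAString).
#' @param internal internal-region consensus.
#' @return list: `sequence`, `regions` (data.frame with 1-based closed
#'   spans of LTR1, internal, LTR2).
#' @export
buildPseudoFullLength <- function(ltr, internal) {
  ltr <- as.character(ltr); internal <- as.character(internal)
  if (!nchar(ltr) || !nchar(internal)) stop("both sequences must be non-empty")
  lL <- nchar(ltr); lI <- nchar(internal)
  list(sequence = paste0(ltr, internal, ltr),
       regions = data.frame(region = c("LTR1", "internal", "LTR2"),
                            start = c(1L, lL + 1L, lL + lI + 1L),
                            end = c(lL, lL + lI, 2L * lL + lI),
                            stringsAsFactors = FALSE))
}

#' Genomic coverage profile of a (pseudo full-length) consensus
#'
#' Searches the consensus against the genome, maps all hits passing the
#' E-value cutoff onto consensus coordinates, accumulates per-position
#' coverage and computes each hit's K2P divergence; hits spanning at least
#' `fullLengthFrac` of the consensus are flagged full-length.
#'
#' @param pseudo consensus sequence (character) or result of
#'   [buildPseudoFullLength()].
#' @param genome DNAStringSet.
#' @param evalueCutoff maximum approximate E-value (default 1e-7).
#' @param minScore minimum hit score.
#' @param fullLengthFrac consensus fraction a hit must span to be flagged
#'   full-length.
#' @return list: `coverage` (integer vector along the consensus), `hits`
#'   (GRanges with `divergence` and `full_length` columns), `regions`
#'   (when a region map was supplied), `consensusLength`.
#' @export
coverageProfile <- function(pseudo, genome, evalueCutoff = 1e-7,
                            minScore = 50, fullLengthFrac = 0.9) {
  regions <- NULL
  if (is.list(pseudo)) { regions <- pseudo$regions; pseudo <- pseudo$sequence }
  pseudo <- as.character(pseudo)
  L <- nchar(pseudo)
  hits <- seedExtendSearch(pseudo, genome, minScore = minScore,
                           queryName = "pseudoERV")
  if (length(hits)) hits <- hits[mcols(hits)$evalue <= evalueCutoff]
  cov <- integer(L)
  if (length(hits)) {
    m <- mcols(hits)
    for (i in seq_along(hits)) {
      span <- m$qstart[i]:m$qend[i]
      cov[span] <- cov[span] + 1L
    }
    div <- vapply(seq_along(hits), function(i)
      as.numeric(kimura2p(m$aln_q[i], m$aln_t[i])), numeric(1))
    mcols(hits)$divergence <- div
    mcols(hits)$full_length <- (m$qend - m$qstart + 1) >= fullLengthFrac * L
  }
  list(coverage = cov, hits = hits, regions = regions, consensusLength = L)
}

#' Classify genomic ERV loci as solo-LTR, full-length or truncated
#'
#' Hits are merged into loci (gaps up to `mergeGap` bp, so fragmented
#' diverged copies are rejoined). A locus is a solo-LTR when at least 80%
#' of its mapped consensus bp falls in the LTR regions and the locus is no
#' longer than 1.5 LTR lengths; full-length when the mapped span covers at
#' least 90% of the consensus; truncated otherwise.
#'
#' @param hits GRanges from [coverageProfile()] (consensus coordinates in
#'   `qstart`/`qend`).
#' @param regions region map from [buildPseudoFullLength()].
#' @param consensusLength total consensus length.
#' @param mergeGap loci closer than this are merged (default 100 bp).
#' @return data.frame: one row per locus with `seqname`, `start`, `end`,
#'   `structure`, `ltr_frac`, `span_frac`, `n_hits`, `divergence` (mean of
#'   member hits).
#' @export
classifyCopyStructure <- function(hits, regions, consensusLength,
                                  mergeGap = 100) {
  if (!length(hits)) return(NULL)
  ltrLen <- regions$end[regions$region == "LTR1"] -
    regions$start[regions$region == "LTR1"] + 1L
  ltrIv <- IRanges(regions$start[regions$region %in% c("LTR1", "LTR2")],
                   regions$end[regions$region %in% c("LTR1", "LTR2")])
  loci <- GenomicRanges::reduce(hits, min.gapwidth = mergeGap + 1L,
                                ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(hits, loci, ignore.strand = TRUE)
  m <- mcols(hits)
  out <- list()
  for (li in seq_along(loci)) {
    idx <- queryHits(ov)[subjectHits(ov) == li]
    spans <- IRanges::reduce(IRanges(m$qstart[idx], m$qend[idx]))
    mapped <- sum(IRanges::width(spans))
    ltrBp <- sum(IRanges::width(IRanges::intersect(spans, ltrIv)))
    spanFrac <- sum(IRanges::width(spans)) / consensusLength
    locusLen <- IRanges::width(loci)[li]
    structure_ <- if (ltrBp / mapped >= 0.8 && locusLen <= 1.5 * ltrLen)
      "solo_LTR"
    else if (spanFrac >= 0.9) "full_length"
    else "truncated"
    dv <- if (!is.null(m$divergence)) mean(m$divergence[idx]) else NA_real_
    out[[li]] <- data.frame(
      seqname = as.character(seqnames(loci))[li],
      start = IRanges::start(loci)[li], end = IRanges::end(loci)[li],
      structure = structure_, ltr_frac = ltrBp / mapped,
      span_frac = spanFrac, n_hits = length(idx), divergence = dv,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Find open reading frames in all six frames
#'
#' An ORF is ATG..stop with at least `minCodons` codons (stop excluded);
#' ORFs still open at the sequence end are reported with `open = TRUE`.
#' Coordinates are 1-based closed on the forward strand and include the
#' stop codon when present.
#'
#' @param seq nucleotide sequence (character/DNAString).
#' @param minCodons minimum ORF length in codons (ATG included, stop
#'   excluded).
#' @return data.frame sorted by decreasing codon count: `frame` (+1..+3,
#'   -1..-3), `start`, `end`, `codons`, `open`.
#' @export
findOrfs <- function(seq, minCodons = 100) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (strandDir in c(1L, -1L)) {
    ss <- if (strandDir == 1L) s else revcompChr(s)
    for (off in 0:2) {
      n <- (L - off) %/% 3
      if (n < 1) next
      st <- off + 1L + 3L * (seq_len(n) - 1L)
      cod <- substring(ss, st, st + 2L)
      isStart <- cod == "ATG"
      isStop <- cod %in% stops
      i <- 1L
      while (i <= n) {
        if (isStart[i]) {
          j <- i
          while (j <= n && !isStop[j]) j <- j + 1L
          open <- j > n
          codons <- (if (open) n else j - 1L) - i + 1L
          if (codons >= minCodons) {
            a <- st[i]
            b <- if (open) st[n] + 2L else st[j] + 2L
            if (strandDir == -1L) { tmp <- L - b + 1L; b <- L - a + 1L; a <- tmp }
            out[[length(out) + 1L]] <- data.frame(
              frame = strandDir * (off + 1L), start = a, end = b,
              codons = codons, open = open, stringsAsFactors = FALSE)
          }
          i <- if (open) n + 1L else j + 1L
        } else i <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0), end = integer(0),
                      codons = integer(0), open = logical(0)))
  df <- do.call(rbind, out)
  df[order(-df$codons, df$frame, df$start), , drop = FALSE]
}
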