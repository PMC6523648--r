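## Seed-and-extend nucleotide homology search and library masking.
##
## Scoring follows BLASTn-like defaults: match +2, mismatch -3, gap open -5,
## gap extend -2.  Seeds are exact 11-mers (single-hit triggering); every
## seed-supported candidate locus is extended with a gapped local alignment
## (Biostrings::pairwiseAlignment).  Approximate E-values use the ungapped
## Karlin-Altschul form with a documented K and are meant for thresholding
## only.

#' Seed-and-extend local search of a query against a genome
#'
#' Both strands are searched. Exact k-mer seed matches are grouped into
#' candidate loci (merged seed diagonals plus padding). Each locus is first
#' extended gaplessly along its seed diagonals (the maximal-scoring segment
#' on the best-supported diagonal); when the seed diagonals indicate an
#' indel — a second diagonal whose gapless segment is disjoint from the
#' best one in both query and target — the locus is re-aligned with a
#' gapped Smith-Waterman-style local alignment of the query against the
#' locus window, and the higher-scoring result wins. One hit is reported
#' per candidate locus.
#'
#' Hits are returned as a GRanges on the genome, sorted by descending score
#' (ties by target start, then query name), with metadata columns `query`,
#' `qstart`, `qend` (1-based closed, forward query orientation), `score`,
#' `pid` (matches / aligned non-gap columns), `evalue`, and the gapped
#' alignment rows `aln_q`/`aln_t`. For minus-strand hits the alignment rows
#' are stored in query (consensus) orientation, i.e. `aln_t` is the reverse
#' complement of the genomic segment.
#'
#' @param query DNAString/character, the query sequence.
#' @param genome DNAStringSet (named) to search.
#' @param k seed length (query must be at least this long).
#' @param minScore minimum alignment score for a reported hit.
#' @param pad bp added around the seed-implied query projection when cutting
#'   the locus window.
#' @param queryName label stored in the `query` column.
#' @param .subjectChars optional precomputed per-sequence character vectors
#'   of the genome (internal; used by callers searching many queries
#'   against one genome).
#' @return GRanges of hits.
#' @export
seedExtendSearch <- function(query, genome, k = 11, minScore = 50, pad = 60,
                             queryName = "query", .subjectChars = NULL) {
  if (is(genome, "DNAString")) genome <- DNAStringSet(setNames(list(genome), "seq"))
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  if (length(genome) && is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  q <- toupper(as.character(query))
  lq <- nchar(q)
  if (lq < k) stop("query shorter than seed length")
  nfrac <- sum(chars(q) == "N") / lq
  if (nfrac > 0.5) stop("query has more than 50% N")
  if (!length(genome) || sum(BiocGenerics::width(genome)) == 0)
    return(emptyHits())
  dblen <- sum(as.numeric(BiocGenerics::width(genome)))

  qf <- q
  qr <- revcompChr(q)
  res <- list()
  for (si in seq_along(genome)) {
    subj <- genome[[si]]
    sname <- names(genome)[si]
    ls <- length(subj)
    schars <- if (!is.null(.subjectChars)) .subjectChars[[sname]]
      else chars(as.character(subj))
    for (str in c("+", "-")) {
      qs <- if (str == "+") qf else qr
      qchars <- chars(qs)
      sd <- seedTable(qs, subj, k)
      if (is.null(sd)) next
      hits <- extendStrand(qchars, schars, sd, lq, ls, k, pad, minScore)
      for (hit in hits) {
        alnQ <- hit$alnQ; alnT <- hit$alnT
        qs1 <- hit$qstart; qe1 <- hit$qend
        if (str == "-") {
          ## report on forward query coordinates; aln rows in query orientation
          tmp <- lq - qe1 + 1L; qe1 <- lq - qs1 + 1L; qs1 <- tmp
          alnQ <- revcompChr(alnQ); alnT <- revcompChr(alnT)
        }
        res[[length(res) + 1L]] <- data.frame(
          seqnames = sname, start = hit$tstart, end = hit$tend, strand = str,
          query = queryName, qstart = qs1, qend = qe1, score = hit$score,
          pid = alignmentPid(alnQ, alnT),
          evalue = approxEvalue(hit$score, lq, dblen),
          aln_q = alnQ, aln_t = alnT, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(emptyHits())
  df <- do.call(rbind, res)
  df <- df[order(-df$score, df$start, df$query), , drop = FALSE]
  gr <- GRanges(df$seqnames, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr) <- DataFrame(df[, c("query", "qstart", "qend", "score", "pid",
                                "evalue", "aln_q", "aln_t")])
  gr
}

emptyHits <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(query = character(0), qstart = integer(0),
                         qend = integer(0), score = numeric(0),
                         pid = numeric(0), evalue = numeric(0),
                         aln_q = character(0), aln_t = character(0))
  gr
}

## exact k-mer seed matches of the query on the subject: (qpos, tpos) table
seedTable <- function(qseq, subj, k) {
  lq <- nchar(qseq)
  st <- seq_len(lq - k + 1L)
  km <- substring(qseq, st, st + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  if (!any(ok)) return(NULL)
  pd <- PDict(DNAStringSet(km[ok]))
  m <- matchPDict(pd, subj)
  n <- S4Vectors::elementNROWS(m)
  if (!sum(n)) return(NULL)
  data.frame(qpos = rep(st[ok], n),
             tpos = unlist(IRanges::start(m), use.names = FALSE))
}

## maximal-scoring gapless segment of the query along diagonal d
## (target pos = query pos + d); returns NULL if the diagonal is empty.
## qlo/qhi restrict the scan to the seed span plus a margin.
gaplessSegment <- function(qchars, schars, d, lq, ls,
                           sc = searchScoring(), qlo = 1L, qhi = lq) {
  q1 <- max(1L, 1L - d, qlo); q2 <- min(lq, ls - d, qhi)
  if (q2 < q1) return(NULL)
  qq <- qchars[q1:q2]
  tt <- schars[(q1 + d):(q2 + d)]
  s <- ifelse(qq == tt & qq %in% BASES, sc$match, sc$mismatch)
  cs <- cumsum(s)
  pre <- cummin(c(0, cs[-length(cs)]))
  gain <- cs - pre
  e <- which.max(gain)
  if (gain[e] <= 0) return(NULL)
  b <- which(c(0, cs)[seq_len(e)] == pre[e])
  b <- b[length(b)]           # segment starts right after the minimal prefix
  qa <- q1 + b - 1L; qb <- q1 + e - 1L
  list(qstart = qa, qend = qb, tstart = qa + d, tend = qb + d,
       score = gain[e],
       alnQ = paste(qchars[qa:qb], collapse = ""),
       alnT = paste(schars[(qa + d):(qb + d)], collapse = ""))
}

## extend all seed groups on one strand of one subject sequence.
## Seeds are grouped by diagonal band (gap <= 50) and then split at target
## jumps larger than the query length; each group is extended gaplessly
## along its best-supported diagonal.  Collinear neighbouring segments
## separated by a small query/target gap (an indel signature) are joined
## with a gapped local alignment.  Finally, candidates whose target span is
## mostly inside a better candidate's span are dropped.
extendStrand <- function(qchars, schars, sd, lq, ls, k, pad, minScore) {
  diag <- sd$tpos - sd$qpos
  o <- order(diag, sd$tpos)
  diag <- diag[o]; tpos <- sd$tpos[o]
  band <- cumsum(c(TRUE, diff(diag) > 50L))
  segs <- list()
  for (b in unique(band)) {
    i <- which(band == b)
    ## split a band where consecutive seeds jump more than a query length
    part <- cumsum(c(TRUE, diff(tpos[i]) > lq + 100L))
    for (p in unique(part)) {
      j <- i[part == p]
      tab <- sort(table(diag[j]), decreasing = TRUE)
      ## every diagonal with >= 2 seeds is a candidate (a small indel keeps
      ## both sides of a copy in one band, on different diagonals); cap at 8
      cand <- as.integer(names(tab)[tab >= 2])
      if (!length(cand)) cand <- as.integer(names(tab)[1])
      for (dbest in head(cand, 8)) {
        qq <- tpos[j][diag[j] == dbest] - dbest
        seg <- gaplessSegment(qchars, schars, dbest, lq, ls,
                              qlo = min(qq) - 400L, qhi = max(qq) + k + 400L)
        if (!is.null(seg)) {
          seg$support <- unname(tab[as.character(dbest)])
          segs[[length(segs) + 1L]] <- seg
        }
      }
    }
  }
  if (!length(segs)) return(list())
  ## drop duplicate segments (same diagonal found via several bands)
  key <- vapply(segs, function(s) paste(s$tstart, s$tend, s$qstart), character(1))
  segs <- segs[!duplicated(key)]
  ## indel join: gapped re-alignment over collinear, nearby segment pairs
  segs <- joinCollinear(segs, qchars, schars, ls, pad)
  ## dedupe: greedy by score, drop candidates mostly covered by a better one
  sc <- vapply(segs, `[[`, numeric(1), "score")
  segs <- segs[order(-sc)]
  kept <- list()
  for (s in segs) {
    if (s$score < minScore) next
    dup <- FALSE
    for (kk in kept) {
      ov <- min(s$tend, kk$tend) - max(s$tstart, kk$tstart) + 1L
      if (ov > 0.5 * (s$tend - s$tstart + 1L)) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- s
  }
  kept
}

## join q/t-collinear segments separated by small gaps via gapped alignment
joinCollinear <- function(segs, qchars, schars, ls, pad) {
  if (length(segs) < 2) return(segs)
  repeat {
    n <- length(segs)
    ts <- vapply(segs, `[[`, numeric(1), "tstart")
    o <- order(ts)
    segs <- segs[o]
    joined <- FALSE
    for (i in seq_len(length(segs) - 1L)) {
      a <- segs[[i]]; b <- segs[[i + 1L]]
      ## only well-seeded segments can witness an indel split
      if (min(a$support %||% 1L, b$support %||% 1L) < 2L) next
      tGap <- b$tstart - a$tend
      qGap <- b$qstart - a$qend
      dA <- a$tstart - a$qstart; dB <- b$tstart - b$qstart
      if (dA == dB) next                       # same diagonal: nothing to join
      if (tGap < -20 || tGap > 300) next
      if (qGap < -20 || qGap > 300) next
      ws <- max(1L, a$tstart - pad); we <- min(ls, b$tend + pad)
      pa <- pairwiseAlignment(DNAString(paste(qchars, collapse = "")),
                              DNAString(paste(schars[ws:we], collapse = "")),
                              type = "local",
                              substitutionMatrix = .tecurSubMat(),
                              gapOpening = 5, gapExtension = 2)
      sc <- BiocGenerics::score(pa)
      if (sc > max(a$score, b$score)) {
        segs[[i]] <- list(qstart = IRanges::start(Biostrings::pattern(pa)),
                          qend = IRanges::end(Biostrings::pattern(pa)),
                          tstart = ws - 1L + IRanges::start(Biostrings::subject(pa)),
                          tend = ws - 1L + IRanges::end(Biostrings::subject(pa)),
                          score = sc,
                          alnQ = as.character(alignedPattern(pa)),
                          alnT = as.character(alignedSubject(pa)),
                          support = (a$support %||% 1L) + (b$support %||% 1L))
        segs[[i + 1L]] <- NULL
        joined <- TRUE
        break
      }
    }
    if (!joined || length(segs) == n) break
  }
  segs
}

#' Resolve overlapping hits, greedily by score
#'
#' Hits are admitted in order of descending score (ties broken by target
#' start, then query name). Later hits overlapping already-covered intervals
#' are trimmed at the overlap boundaries; resulting fragments shorter than
#' `minFragment` bp are dropped. Fragment alignments, scores and identities
#' are recomputed from the sliced alignment columns.
#'
#' @param hits GRanges as returned by [seedExtendSearch()].
#' @param minFragment minimum retained fragment width in bp.
#' @return GRanges of disjoint hits (per sequence), sorted by position.
#' @export
resolveOverlaps <- function(hits, minFragment = 20) {
  if (!length(hits)) return(hits)
  ord <- order(-mcols(hits)$score, IRanges::start(hits),
               mcols(hits)$query, method = "radix")
  hits <- hits[ord]
  out <- list()
  covered <- list()   # per seqname IRanges
  for (i in seq_along(hits)) {
    h <- hits[i]
    sn <- as.character(seqnames(h))
    cov <- covered[[sn]]
    if (is.null(cov)) cov <- IRanges()
    frs <- IRanges::setdiff(IRanges(IRanges::start(h), IRanges::end(h)), cov)
    frs <- frs[IRanges::width(frs) >= minFragment]
    if (!length(frs)) next
    for (j in seq_along(frs)) {
      fh <- sliceHit(h, IRanges::start(frs)[j], IRanges::end(frs)[j])
      if (!is.null(fh)) out[[length(out) + 1L]] <- fh
    }
    covered[[sn]] <- IRanges::union(cov, frs)
  }
  if (!length(out)) return(emptyHits())
  res <- do.call(c, out)
  res[order(as.character(seqnames(res)), IRanges::start(res))]
}

## restrict a hit to target subinterval [s, e]; recompute alignment slices
sliceHit <- function(h, s, e) {
  hs <- IRanges::start(h); he <- IRanges::end(h)
  if (s <= hs && e >= he) return(h)
  m <- mcols(h)
  str <- as.character(strand(h))
  tpos <- alignmentTargetPos(m$aln_t, hs, he, str)
  keep <- tpos >= s & tpos <= e
  tc <- chars(m$aln_t)
  ## drop leading gap columns that inherited the previous base's position
  firstReal <- which(keep & tc != "-")
  if (!length(firstReal)) return(NULL)
  keep[seq_len(firstReal[1] - 1L)] <- FALSE
  alnQ <- paste(chars(m$aln_q)[keep], collapse = "")
  alnT <- paste(tc[keep], collapse = "")
  qpos <- alignmentQueryPos(m$aln_q, m$qstart)[keep]
  qc <- chars(m$aln_q)[keep]
  qreal <- qpos[qc != "-"]
  if (!length(qreal)) return(NULL)
  gr <- GRanges(seqnames(h), IRanges(s, e), strand = str)
  mcols(gr) <- DataFrame(query = m$query, qstart = min(qreal), qend = max(qreal),
                         score = scoreAlignment(alnQ, alnT),
                         pid = alignmentPid(alnQ, alnT), evalue = m$evalue,
                         aln_q = alnQ, aln_t = alnT)
  gr
}

#' Mask a genome with a consensus library
#'
#' Runs [seedExtendSearch()] for every library consensus, keeps hits at or
#' above `minScore`, resolves overlaps with [resolveOverlaps()] and labels
#' each retained hit with its consensus name and classification path.
#'
#' @param library a [ConsensusLibrary-class] (unique names required).
#' @param genome DNAStringSet.
#' @param minScore minimum hit score (default 225).
#' @param k seed length.
#' @return a [MaskTrack-class].
#' @export
maskGenome <- function(library, genome, minScore = 225, k = 11) {
  stopifnot(is(library, "ConsensusLibrary"), length(library) > 0)
  if (anyDuplicated(names(library))) stop("duplicate consensus names in library")
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  seqs <- as.character(consensusSeqs(library))
  sChars <- lapply(setNames(seq_along(genome), names(genome)), function(i)
    chars(as.character(genome[[i]])))
  all <- lapply(seq_along(seqs), function(i)
    seedExtendSearch(seqs[[i]], genome, k = k, minScore = minScore,
                     queryName = names(seqs)[i], .subjectChars = sChars))
  hits <- do.call(c, all)
  resolved <- resolveOverlaps(hits)
  new("MaskTrack", hits = resolved,
      genomeLength = sum(as.numeric(BiocGenerics::width(genome))),
      seqLengths = setNames(BiocGenerics::width(genome), names(genome)),
      library = consensusInfo(library)[, c("name", "class", "superfamily",
                                           "family", "subfamily")])
}
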