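## Automated consensus curation: collect best hits with flanks, anchor them
## in a common consensus coordinate frame, find the homologous core, build a
## majority-rule consensus with the CpG restoration rule, call boundaries,
## TSDs, LTR terminal motifs and the CR1 3' octamer, and extend CR1
## consensuses in the 5' direction while enough copies support it.

#' Select predicted consensuses for curation
#'
#' Keeps predicted consensuses that are more than 5% diverged from every
#' known consensus: an entry is dropped when its best local alignment to any
#' known sequence reaches `maxIdentity` (0.95) identity over the aligned
#' region.
#'
#' @param predicted,known [ConsensusLibrary-class] objects.
#' @param maxIdentity identity at or above which an entry is considered
#'   already annotated.
#' @return the filtered predicted library.
#' @export
selectForCuration <- function(predicted, known, maxIdentity = 0.95) {
  if (is.null(known) || !length(known)) return(predicted)
  kseqs <- consensusSeqs(known)
  keep <- vapply(seq_len(length(predicted)), function(i) {
    h <- seedExtendSearch(as.character(consensusSeqs(predicted)[[i]]), kseqs,
                          minScore = 50, queryName = names(predicted)[i])
    !length(h) || max(mcols(h)$pid) < maxIdentity
  }, logical(1))
  predicted[keep]
}

#' Collect the best hits of a consensus on a genome, with flanks
#'
#' The top `n` hits by score are retained after removing hits overlapping a
#' better hit on the genome (duplicate loci). Each retained hit is returned
#' with `flank` bp of genomic context on each side; minus-strand rows are
#' reverse complemented so all rows are in consensus orientation.
#'
#' @param consensus character/DNAString seed consensus.
#' @param genome DNAStringSet.
#' @param n number of hits to keep (at least 2 must be found).
#' @param flank flank length in bp.
#' @param minScore minimum hit score.
#' @param name element name used in messages.
#' @return list of flanked-hit records: `hit` (GRanges row), `row`
#'   (character sequence in consensus orientation), `lf`, `rf` (realized
#'   flank lengths).  Signals a `tecur_uncuratable` condition when fewer
#'   than two hits are found.
#' @export
collectHits <- function(consensus, genome, n = 20, flank = 2000,
                        minScore = 50, name = "element",
                        .subjectChars = NULL) {
  stopifnot(n >= 2)
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  hits <- seedExtendSearch(as.character(consensus), genome,
                           minScore = minScore, queryName = name,
                           .subjectChars = .subjectChars)
  if (length(hits) >= 2) {
    keep <- rep(TRUE, length(hits))   # hits are sorted by descending score
    for (i in seq_along(hits)[-1]) {
      prev <- hits[which(keep[seq_len(i - 1L)])]
      if (length(prev) &&
          any(IRanges::overlapsAny(hits[i], prev, ignore.strand = TRUE)))
        keep[i] <- FALSE
    }
    hits <- hits[keep]
  }
  if (length(hits) < 2) uncuratable(name, sprintf("only %d hit(s) found", length(hits)))
  hits <- head(hits, n)
  out <- vector("list", length(hits))
  for (i in seq_along(hits)) {
    h <- hits[i]
    sn <- as.character(seqnames(h))
    ls <- length(genome[[sn]])
    ts <- IRanges::start(h); te <- IRanges::end(h)
    rs <- max(1L, ts - flank); re <- min(ls, te + flank)
    row <- as.character(subseq(genome[[sn]], rs, re))
    if (as.character(strand(h)) == "-") {
      row <- revcompChr(row)
      lf <- re - te; rf <- ts - rs
    } else {
      lf <- ts - rs; rf <- re - te
    }
    out[[i]] <- list(hit = h, row = row, lf = lf, rf = rf)
  }
  out
}

#' Anchor flanked hits in a consensus coordinate frame
#'
#' Builds a [CurationAlignment-class]: each row's hit alignment places its
#' aligned characters at the consensus positions of the hit (insertions
#' relative to the consensus are dropped; deletions appear as `-`), and the
#' flanks are laid out by coordinate offset on either side. Column `c`
#' corresponds to consensus position `c - flank`.
#'
#' @param flanked list from [collectHits()].
#' @param consensusLength length of the seed consensus.
#' @param flank flank size used during collection.
#' @param name consensus name.
#' @return a [CurationAlignment-class].
#' @export
buildCurationAlignment <- function(flanked, consensusLength, flank = 2000,
                                   name = "element") {
  nr <- length(flanked)
  nc <- consensusLength + 2L * flank
  mat <- matrix(".", nr, nc)
  core <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    fh <- flanked[[r]]
    m <- mcols(fh$hit)
    qc <- chars(m$aln_q); tc <- chars(m$aln_t)
    qpos <- alignmentQueryPos(m$aln_q, m$qstart)
    keep <- qc != "-"
    cols <- qpos[keep] + flank
    mat[r, cols] <- tc[keep]
    core[r, cols] <- TRUE
    rowc <- chars(fh$row)
    nCoreT <- sum(tc != "-")
    if (fh$lf > 0) {
      cl <- (m$qstart - fh$lf):(m$qstart - 1L) + flank
      ok <- cl >= 1L
      mat[r, cl[ok]] <- rowc[seq_len(fh$lf)][ok]
    }
    if (fh$rf > 0) {
      cr <- (m$qend + 1L):(m$qend + fh$rf) + flank
      ok <- cr <= nc
      mat[r, cr[ok]] <- rowc[(fh$lf + nCoreT + 1L):(fh$lf + nCoreT + fh$rf)][ok]
    }
  }
  new("CurationAlignment", mat = mat, isCore = core, offset = as.integer(flank),
      consensusName = name,
      hits = do.call(c, lapply(flanked, `[[`, "hit")))
}

## per-column agreement fraction among rows aligned (core) at the column
columnAgreement <- function(mat, core) {
  syms <- c(BASES, "-")
  cnt <- vapply(syms, function(s) colSums(core & mat == s), numeric(ncol(mat)))
  ncov <- rowSums(cnt)
  agree <- rowSums(cnt * (cnt - 1) / 2)
  tot <- ncov * (ncov - 1) / 2
  list(frac = ifelse(tot > 0, agree / tot, 0), ncov = ncov)
}

## extend a boundary through flank space while >= minSupport rows stay
## >= identity to the window majority; promotes supporting cells to core.
## The majority is computed over the rows that supported the previous
## window (the "trusted" set) so a few unrelated flanks cannot dilute it —
## this mirrors a curator following the copies that keep aligning.
## Returns list(aln, bound, steps, unanimous).
extendThroughFlank <- function(aln, bound, direction, minSupport = 2,
                               identity = 0.8, window = 20) {
  mat <- aln@mat; core <- aln@isCore
  nc <- ncol(mat)
  steps <- 0L
  unanimous <- FALSE
  trusted <- seq_len(nrow(mat))
  repeat {
    w <- if (direction < 0) (bound - window):(bound - 1L) else (bound + 1L):(bound + window)
    w <- w[w >= 1L & w <= nc]
    if (length(w) < 5L) break
    sub <- mat[, w, drop = FALSE]
    present <- sub != "."
    if (!any(present)) break
    majRows <- if (sum(rowSums(present[trusted, , drop = FALSE]) > 0) >= 2)
      trusted else seq_len(nrow(mat))
    maj <- apply(sub[majRows, , drop = FALSE], 2, function(col) {
      col <- col[col %in% BASES]
      if (!length(col)) NA_character_ else names(which.max(table(factor(col, BASES))))
    })
    okMaj <- !is.na(maj)
    if (sum(okMaj) < length(w) * 0.5) break
    rowsFull <- rowSums(present) >= length(w) * 0.9
    ident <- vapply(seq_len(nrow(sub)), function(r) {
      use <- present[r, ] & okMaj
      if (!sum(use)) return(0)
      sum(sub[r, use] == maj[use]) / sum(use)
    }, numeric(1))
    supp <- which(rowsFull & ident >= identity)
    if (length(supp) < minSupport) break
    if (length(supp) >= 0.9 * nrow(mat)) unanimous <- TRUE
    for (r in supp) core[r, w] <- TRUE
    trusted <- supp
    bound <- if (direction < 0) min(w) else max(w)
    steps <- steps + length(w)
    if ((direction < 0 && bound <= 1L) || (direction > 0 && bound >= nc)) break
  }
  aln@isCore <- core
  list(aln = aln, bound = bound, steps = steps, unanimous = unanimous)
}

## column-by-column boundary polish: recover the few element-terminal bases
## that fall beyond the hit alignments (e.g. when the seed's terminal base
## was mutated, every hit stops short of the true element edge)
polishBoundary <- function(aln, bound, direction, maxCols = 15L,
                           minPresent = 3L, minAgree = 0.7) {
  mat <- aln@mat; core <- aln@isCore
  nc <- ncol(mat)
  minPresent <- min(minPresent, nrow(mat))
  cc <- bound
  weak <- integer(0)     # columns skipped as mutation hotspots
  for (s in seq_len(maxCols)) {
    cc <- cc + direction
    if (cc < 1L || cc > nc) break
    col <- mat[, cc]
    present <- which(col %in% BASES)
    if (length(present) < minPresent) break
    tab <- table(factor(col[present], BASES))
    maj <- names(which.max(tab))
    agree <- present[col[present] == maj]
    if (length(agree) / length(present) < minAgree) {
      weak <- c(weak, cc)
      if (length(weak) > 2L) break
      next
    }
    ## a passing column also validates the skipped hotspot columns
    for (wc in weak) {
      colw <- mat[, wc]
      pw <- which(colw %in% BASES)
      majw <- names(which.max(table(factor(colw[pw], BASES))))
      core[pw[colw[pw] == majw], wc] <- TRUE
    }
    weak <- integer(0)
    core[agree, cc] <- TRUE
    bound <- cc
  }
  aln@isCore <- core
  list(aln = aln, bound = bound)
}

#' Detect element boundaries in a curation alignment
#'
#' Inside the element, copies are homologous; in the flanks they are
#' unrelated. The homologous core is the maximal column range whose
#' 20-column sliding window keeps at least `minPairFrac` of row pairs in
#' agreement (computed over characters placed by the hit alignments). Edges
#' are then refined column-wise, and finally the boundary is allowed to
#' extend through flank space while at least `extendMinSupport` rows remain
#' at least 80% identical to the window majority — this both recovers element
#' sequence beyond a truncated seed and exposes the degenerate case of
#' copies sharing identical flanks (flagged `ambiguous-boundary`).
#'
#' @param aln a [CurationAlignment-class].
#' @param window sliding window width in columns.
#' @param minPairFrac minimum fraction of agreeing row pairs.
#' @param extendMinSupport rows required to extend a boundary into flanks.
#' @param extendIdentity per-row identity to the window majority.
#' @return list with `start`, `end` (columns), `flags` (character vector),
#'   `aln` (alignment with promoted cells), `agreement` (per-column
#'   fraction). Signals `tecur_uncuratable` if no window passes.
#' @export
detectBoundaries <- function(aln, window = 20, minPairFrac = 0.7,
                             extendMinSupport = NULL, extendIdentity = 0.8) {
  if (is.null(extendMinSupport)) extendMinSupport <- min(3L, nrow(aln@mat))
  ca <- columnAgreement(aln@mat, aln@isCore)
  frac <- ca$frac; ncov <- ca$ncov
  sm <- as.numeric(stats::filter(frac, rep(1 / window, window), sides = 2))
  sm[is.na(sm)] <- 0
  pass <- which(sm >= minPairFrac & ncov >= 2)
  if (!length(pass)) uncuratable(aln@consensusName, "no homologous core")
  c1 <- min(pass); c2 <- max(pass)
  while (c1 < c2 && (frac[c1] < 0.5 || ncov[c1] < 2)) c1 <- c1 + 1L
  while (c2 > c1 && (frac[c2] < 0.5 || ncov[c2] < 2)) c2 <- c2 - 1L
  ## walk the edges outward column by column, tolerating up to two
  ## consecutive weak columns (mutation hotspots such as CpG sites sit
  ## right up against element ends often enough to matter)
  walkOut <- function(bound, dir) {
    weak <- 0L
    j <- bound
    repeat {
      j <- j + dir
      if (j < 1L || j > ncol(aln@mat)) break
      if (ncov[j] >= 2 && frac[j] >= 0.5) { bound <- j; weak <- 0L }
      else { weak <- weak + 1L; if (weak > 2L || ncov[j] < 2) break }
    }
    bound
  }
  c1 <- walkOut(c1, -1L)
  c2 <- walkOut(c2, +1L)
  flags <- character(0)
  e5 <- extendThroughFlank(aln, c1, -1L, extendMinSupport, extendIdentity)
  aln <- e5$aln
  e3 <- extendThroughFlank(aln, c2, +1L, extendMinSupport, extendIdentity)
  aln <- e3$aln
  p5 <- polishBoundary(aln, e5$bound, -1L)
  aln <- p5$aln
  p3 <- polishBoundary(aln, e3$bound, +1L)
  aln <- p3$aln
  if (e5$steps + e3$steps > 0) flags <- c(flags, "extended")
  if (p5$bound <= 1L || p3$bound >= ncol(aln@mat))
    flags <- c(flags, "flank-exhausted")
  if ((e5$unanimous && e5$steps > 100) || (e3$unanimous && e3$steps > 100))
    flags <- c(flags, "ambiguous-boundary")
  if (all(ncov[c(1, ncol(aln@mat))] >= 2))
    flags <- c(flags, "full-width")
  list(start = p5$bound, end = p3$bound, flags = flags, aln = aln,
       agreement = frac)
}

#' Majority-rule consensus with CpG restoration
#'
#' For every column in `cols`, the most frequent non-gap base among rows
#' aligned at the column wins; a gap wins (and the column is dropped) only
#' when gaps exceed half the aligned rows. Ties are broken in the fixed
#' order A < C < G < T so consensuses are byte-stable. With `cpgRule` on,
#' adjacent columns whose two most frequent dinucleotide patterns are
#' \{CG, TG\} or \{CG, CA\} — with CG supported by at least two rows and at
#' least a quarter of the rows carrying both columns — are emitted as `CG`
#' even when TG/CA is the plurality, restoring hypermutable CpG sites (the
#' quarter floor keeps sporadic transitions at ordinary TpG/CpA sites from
#' being miscalled as CpG).
#'
#' @param aln a [CurationAlignment-class] (after boundary detection).
#' @param cols integer vector of columns (e.g. `start:end` from
#'   [detectBoundaries()]).
#' @param cpgRule logical; apply the CpG restoration rule.
#' @return list: `sequence` (character), `columns` (columns retained, in
#'   order), `depth` (aligned rows per retained column), `cpgRestored`
#'   (columns altered by the rule).
#' @export
buildConsensus <- function(aln, cols, cpgRule = TRUE) {
  mat <- aln@mat[, cols, drop = FALSE]
  core <- aln@isCore[, cols, drop = FALSE]
  syms <- c(BASES, "-")
  cnt <- vapply(syms, function(s) colSums(core & mat == s), numeric(length(cols)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, syms))
  ncov <- rowSums(cnt)
  gapWin <- cnt[, "-"] > ncov / 2
  keep <- ncov > 0 & !gapWin
  baseIdx <- apply(cnt[, BASES, drop = FALSE], 1, which.max)  # ties: A<C<G<T
  call <- BASES[baseIdx]
  kept <- which(keep)
  call <- call[kept]
  colsKept <- cols[kept]
  cpgRestored <- integer(0)
  if (cpgRule && length(kept) > 1) {
    for (i in seq_len(length(kept) - 1L)) {
      if (colsKept[i + 1L] != colsKept[i] + 1L) next
      pair <- paste0(call[i], call[i + 1L])
      if (!pair %in% c("TG", "CA", "TA")) next
      c1 <- kept[i]; c2 <- kept[i + 1L]
      rows <- core[, c1] & core[, c2] & mat[, c1] %in% BASES & mat[, c2] %in% BASES
      if (!sum(rows)) next
      pats <- paste0(mat[rows, c1], mat[rows, c2])
      tab <- sort(table(pats), decreasing = TRUE)
      nCG <- sum(pats == "CG")
      if (nCG < 2) next
      top2 <- names(tab)[seq_len(min(2, length(tab)))]
      ## two signatures of a hypermutable CpG: (a) CG is one of the two
      ## dominant patterns alongside its deamination product; (b) at high
      ## divergence, all three single/double deamination products co-occur
      ## with CG (TG and CA cannot both arise from a non-CpG ancestor)
      restore <- (pair != "TA" && setequal(top2, c("CG", pair)) &&
                    nCG >= max(2, 0.25 * length(pats))) ||
        (sum(pats == "TG") >= 2 && sum(pats == "CA") >= 2)
      if (restore) {
        call[i] <- "C"; call[i + 1L] <- "G"
        cpgRestored <- c(cpgRestored, colsKept[i], colsKept[i + 1L])
      }
    }
  }
  list(sequence = paste(call, collapse = ""), columns = colsKept,
       depth = ncov[kept], cpgRestored = cpgRestored)
}

## genomic position of an alignment column for one row (no-indel arithmetic
## in flank space, alignment map inside the hit span)
rowColToGenomic <- function(aln, r, colv) {
  h <- aln@hits[r]
  m <- mcols(h)
  off <- aln@offset
  ts <- IRanges::start(h); te <- IRanges::end(h)
  str <- as.character(strand(h))
  qpos <- alignmentQueryPos(m$aln_q, m$qstart)
  tpos <- alignmentTargetPos(m$aln_t, ts, te, str)
  qc <- chars(m$aln_q)
  map <- tpos[qc != "-"]
  names(map) <- as.character(qpos[qc != "-"] + off)
  vapply(colv, function(cc) {
    key <- as.character(cc)
    if (key %in% names(map)) return(unname(map[key]))
    cpos <- cc - off
    if (cpos < m$qstart) {
      d <- m$qstart - cpos
      if (str == "+") ts - d else te + d
    } else {
      d <- cpos - m$qend
      if (str == "+") te + d else ts - d
    }
  }, numeric(1))
}

## rows spanning [c1, c2] (within tol) and their genomic element intervals
rowElementIntervals <- function(aln, c1, c2, tol = 3L) {
  nr <- nrow(aln@mat)
  out <- list()
  for (r in seq_len(nr)) {
    cc <- which(aln@isCore[r, ])
    if (!length(cc)) next
    if (min(cc) > c1 + tol || max(cc) < c2 - tol) next
    g <- rowColToGenomic(aln, r, c(max(c1, min(cc)), min(c2, max(cc))))
    out[[length(out) + 1L]] <- data.frame(
      row = r, seqname = as.character(seqnames(aln@hits[r])),
      start = min(g), end = max(g),
      strand = as.character(strand(aln@hits[r])), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect a target site duplication around an element interval
#'
#' For each k in `kSet`, tests whether the k-mer immediately left of the
#' element equals the k-mer immediately right of it, sliding each boundary
#' independently within `jitter` bp. All matching combinations are
#' reported; the best call is the maximal k at the smallest total boundary
#' offset.
#'
#' @param genome DNAStringSet.
#' @param seqname,start,end element interval (1-based closed, excluding the
#'   TSD).
#' @param kSet candidate TSD lengths.
#' @param jitter boundary slack in bp.
#' @return list: `matches` (data.frame k/offL/offR/seq) and `best` (list
#'   with `k` and `seq`, or NULL).
#' @export
detectTSD <- function(genome, seqname, start, end, kSet = 4:6, jitter = 2) {
  g <- genome[[seqname]]
  ls <- length(g)
  kmax <- max(kSet)
  if (start - kmax - jitter < 1 || end + kmax + jitter > ls)
    return(list(matches = NULL, best = NULL))
  res <- list()
  for (k in sort(kSet, decreasing = TRUE)) {
    for (offL in -jitter:jitter) for (offR in -jitter:jitter) {
      left <- as.character(subseq(g, start - k + offL, start - 1L + offL))
      right <- as.character(subseq(g, end + 1L + offR, end + k + offR))
      if (left == right)
        res[[length(res) + 1L]] <- data.frame(k = k, offL = offL, offR = offR,
                                              seq = left, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(list(matches = NULL, best = NULL))
  df <- do.call(rbind, res)
  df <- df[order(abs(df$offL) + abs(df$offR), -df$k), , drop = FALSE]
  list(matches = df, best = list(k = df$k[1], seq = df$seq[1]))
}

#' Check LTR terminal dinucleotides
#'
#' @param seq consensus sequence (character/DNAString).
#' @return list: `end5`, `end3`, `canonical` (TG...CA), `variant` (NA when
#'   canonical, otherwise "XX...YY").
#' @export
checkLtrEnds <- function(seq) {
  s <- as.character(seq)
  L <- nchar(s)
  if (L < 4) stop("sequence too short for terminal dinucleotides")
  e5 <- substr(s, 1, 2); e3 <- substr(s, L - 1, L)
  canonical <- e5 == "TG" && e3 == "CA"
  list(end5 = e5, end3 = e3, canonical = canonical,
       variant = if (canonical) NA_character_ else paste0(e5, "...", e3))
}

#' Locate the CR1 3'-terminal octamer
#'
#' Finds the rightmost match of `ATTCTRTG` (R = A or G) within the final
#' `window` bp of the consensus.
#'
#' @param seq consensus sequence.
#' @param window 3' window searched, in bp.
#' @return 1-based start position of the motif, or NULL if absent.
#' @export
findCr1ThreePrime <- function(seq, window = 50) {
  s <- as.character(seq)
  L <- nchar(s)
  from <- max(1L, L - window + 1L)
  tail <- substr(s, from, L)
  m <- gregexpr("ATTCT[AG]TG", tail)[[1]]
  if (m[1] == -1) return(NULL)
  from + m[length(m)] - 1L
}

#' Extend a CR1 consensus in the 5' direction
#'
#' Re-collects hits with flanks and extends the consensus 5'-ward while at
#' least `minSupport` rows remain >= 80% identical to the column majority in
#' each newly added window; iterates (re-search with the extended consensus)
#' when an extension exhausts the available flank. Terminates because the
#' consensus is bounded by the longest genomic copy plus flank.
#'
#' @param consensus character seed consensus (3'-anchored).
#' @param genome DNAStringSet.
#' @param minSupport rows required to keep extending (default 3).
#' @param window extension window in columns.
#' @param flank,n,minScore hit collection parameters.
#' @param maxIter maximum re-collection rounds.
#' @param name element name.
#' @return list: `consensus` (extended sequence), `extended` (bp added),
#'   `iterations`.
#' @export
extendFivePrime <- function(consensus, genome, minSupport = 3, window = 50,
                            flank = 2000, n = 20, minScore = 50, maxIter = 4,
                            name = "element", .subjectChars = NULL) {
  cons <- as.character(consensus)
  total <- 0L
  for (iter in seq_len(maxIter)) {
    fl <- collectHits(cons, genome, n = n, flank = flank,
                      minScore = minScore, name = name,
                      .subjectChars = .subjectChars)
    aln <- buildCurationAlignment(fl, nchar(cons), flank, name)
    bd <- detectBoundaries(aln, extendMinSupport = minSupport)
    ## re-run the 5' extension with the CR1 support rule and a wider window
    ext <- extendThroughFlank(bd$aln, bd$start, -1L, minSupport = minSupport,
                              identity = 0.8, window = window)
    cns <- buildConsensus(ext$aln, ext$bound:bd$end)
    added <- nchar(cns$sequence) - nchar(cons)
    newCons <- cns$sequence
    if (nchar(newCons) <= nchar(cons) && iter > 1) break
    grew <- nchar(newCons) > nchar(cons)
    total <- total + max(0L, nchar(newCons) - nchar(cons))
    cons <- newCons
    ## stop unless the extension ran into the start of the alignment matrix
    if (!grew || ext$bound > window + 1L) break
  }
  list(consensus = cons, extended = total, iterations = iter)
}

#' Curate one element from a seed consensus
#'
#' Runs the full single-element curation procedure: best-hit collection with
#' 2-kb flanks, consensus-anchored alignment, boundary detection,
#' majority-rule consensus with CpG restoration, element class recognition
#' (CR1 3' octamer => CR1 with 5' extension; otherwise TSD/LTR-end checks),
#' per-copy TSD detection and aggregation, and LTR terminal snapping to
#' TG...CA within 3 bp when present.
#'
#' @param seed character/DNAString seed consensus.
#' @param genome DNAStringSet.
#' @param name element name.
#' @param n,flank,minScore hit collection parameters.
#' @param cpgRule apply the CpG restoration rule.
#' @param classHint optional class ("LTR", "LINE/CR1", ...) to skip
#'   auto-recognition.
#' @param minSupport CR1 extension support threshold.
#' @return list: `sequence`, `class`, `tsd` (integer vector of supported TSD
#'   lengths), `tsdCalls` (per-copy best k), `ends` ([checkLtrEnds()]
#'   result), `cr1MotifPos`, `nHits`, `flags`, `boundaries`; or, when the
#'   element is uncuratable, a list with `uncuratable = TRUE` and `reason`.
#' @export
curateFamily <- function(seed, genome, name = "element", n = 20, flank = 2000,
                         minScore = 50, cpgRule = TRUE, classHint = NULL,
                         minSupport = 3, .subjectChars = NULL) {
  res <- tryCatch({
    fl <- collectHits(seed, genome, n = n, flank = flank,
                      minScore = minScore, name = name,
                      .subjectChars = .subjectChars)
    aln <- buildCurationAlignment(fl, nchar(as.character(seed)), flank, name)
    bd <- detectBoundaries(aln)
    cns <- buildConsensus(bd$aln, bd$start:bd$end, cpgRule = cpgRule)
    seqv <- cns$sequence
    flags <- bd$flags
    cr1pos <- findCr1ThreePrime(seqv)

    ## LTR evidence on the initial consensus: snapped TG...CA termini plus
    ## per-copy TSD support.  An LTR element can carry the CR1 octamer near
    ## its 3' end by chance, so structural evidence takes precedence and
    ## the CR1 path requires the motif with no LTR support.
    snap <- snapLtrEnds(seqv)
    ends0 <- if (nchar(snap$sequence) >= 4) checkLtrEnds(snap$sequence) else NULL
    iv0 <- rowElementIntervals(bd$aln, bd$start + snap$trim5,
                               bd$end - snap$trim3)
    calls0 <- integer(0)
    if (!is.null(iv0)) {
      for (i in seq_len(nrow(iv0))) {
        td <- detectTSD(genome, iv0$seqname[i], iv0$start[i], iv0$end[i])
        if (!is.null(td$best)) calls0 <- c(calls0, td$best$k)
      }
    }
    tsd0 <- integer(0)
    if (length(calls0)) {
      tab <- table(calls0)
      tsd0 <- sort(as.integer(names(tab)[tab >= max(2, 0.25 * length(calls0))]))
    }
    ltrEvidence <- length(tsd0) > 0 && !is.null(ends0) && ends0$canonical
    isCR1 <- if (!is.null(classHint)) classHint == "LINE/CR1"
      else !is.null(cr1pos) && !ltrEvidence

    if (isCR1) {
      ext <- extendFivePrime(seqv, genome, minSupport = minSupport,
                             flank = flank, n = n, minScore = minScore,
                             name = name, .subjectChars = .subjectChars)
      seqv <- ext$consensus
      cr1pos <- findCr1ThreePrime(seqv, window = 60)
      if (!is.null(cr1pos) && cr1pos + 7L < nchar(seqv))
        seqv <- substr(seqv, 1, cr1pos + 7L)   # the octamer ends the element
      return(list(sequence = seqv, class = "LINE/CR1", tsd = integer(0),
                  tsdCalls = integer(0), ends = NULL, cr1MotifPos = cr1pos,
                  nHits = length(fl), flags = flags,
                  boundaries = c(bd$start, bd$end),
                  extended = ext$extended))
    }

    ## LTR candidate: keep the snapped termini and the TSD calls from above
    seqv <- snap$sequence
    b1 <- bd$start + snap$trim5; b2 <- bd$end - snap$trim3
    cls <- if (length(tsd0) && !is.null(ends0)) "LTR" else "Unknown"
    list(sequence = seqv, class = cls, tsd = tsd0, tsdCalls = calls0,
         ends = ends0, cr1MotifPos = NULL, nHits = length(fl), flags = flags,
         boundaries = c(b1, b2))
  }, tecur_uncuratable = function(e)
    list(uncuratable = TRUE, reason = conditionMessage(e)))
  res
}

## trim up to 3 bp per end so the consensus starts TG and ends CA, when the
## motifs are present nearby (curators use TG...CA to fix LTR boundaries)
snapLtrEnds <- function(seqv) {
  s <- chars(seqv)
  L <- length(s)
  trim5 <- 0L; trim3 <- 0L
  if (L >= 10) {
    if (!(s[1] == "T" && s[2] == "G")) {
      for (i in 1:3) if (s[i + 1] == "T" && s[i + 2] == "G") { trim5 <- i; break }
    }
    if (!(s[L - 1] == "C" && s[L] == "A")) {
      for (i in 1:3) if (s[L - i - 1] == "C" && s[L - i] == "A") { trim3 <- i; break }
    }
  }
  list(sequence = paste(s[(1 + trim5):(L - trim3)], collapse = ""),
       trim5 = trim5, trim3 = trim3)
}

#' Curate a library of seed consensuses against a genome
#'
#' Applies [selectForCuration()] (when `known` is given) and then
#' [curateFamily()] to every seed, assembling the curated consensuses into a
#' [ConsensusLibrary-class] plus a per-element report.
#'
#' @param seeds [ConsensusLibrary-class] of predicted consensuses.
#' @param genome DNAStringSet.
#' @param known optional [ConsensusLibrary-class] of already-annotated
#'   repeats.
#' @param ... passed to [curateFamily()].
#' @return list: `library` ([ConsensusLibrary-class] of curated elements),
#'   `report` (data.frame with per-element curation details, including
#'   uncuratable reasons).
#' @export
curateLibrary <- function(seeds, genome, known = NULL, ...) {
  seeds <- selectForCuration(seeds, known)
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  gChars <- lapply(setNames(seq_along(genome), names(genome)), function(i)
    chars(as.character(genome[[i]])))
  recs <- list(); rows <- list()
  for (i in seq_len(length(seeds))) {
    nm <- names(seeds)[i]
    r <- curateFamily(as.character(consensusSeqs(seeds)[[i]]), genome,
                      name = nm, .subjectChars = gChars, ...)
    if (isTRUE(r$uncuratable)) {
      rows[[nm]] <- data.frame(name = nm, class = NA, length = NA, n_hits = NA,
                               tsd = NA, end5 = NA, end3 = NA,
                               cr1_motif_pos = NA, flags = "uncuratable",
                               reason = r$reason, stringsAsFactors = FALSE)
      next
    }
    recs[[nm]] <- r
    rows[[nm]] <- data.frame(
      name = nm, class = r$class, length = nchar(r$sequence),
      n_hits = r$nHits, tsd = paste(r$tsd, collapse = ","),
      end5 = if (is.null(r$ends)) NA else r$ends$end5,
      end3 = if (is.null(r$ends)) NA else r$ends$end3,
      cr1_motif_pos = if (is.null(r$cr1MotifPos)) NA_integer_ else r$cr1MotifPos,
      flags = paste(r$flags, collapse = ";"), reason = NA,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!length(recs))
    return(list(library = NULL, report = report))
  seqs <- DNAStringSet(vapply(recs, `[[`, character(1), "sequence"))
  info <- DataFrame(
    name = names(recs),
    class = vapply(recs, `[[`, character(1), "class"),
    superfamily = vapply(recs, function(r)
      superfamilyFromTSD(r$tsd)$superfamily, character(1)),
    family = names(recs), subfamily = names(recs),
    tsd_length = vapply(recs, function(r) paste(r$tsd, collapse = ","),
                        character(1)),
    end5 = vapply(recs, function(r)
      if (is.null(r$ends)) NA_character_ else r$ends$end5, character(1)),
    end3 = vapply(recs, function(r)
      if (is.null(r$ends)) NA_character_ else r$ends$end3, character(1)),
    cr1_motif_pos = vapply(recs, function(r)
      if (is.null(r$cr1MotifPos)) NA_integer_ else as.integer(r$cr1MotifPos),
      integer(1)),
    source = "curated", n_hits = vapply(recs, `[[`, numeric(1), "nHits"))
  list(library = ConsensusLibrary(seqs, info), report = report)
}
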