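## FASTA / BED / GFF3 / report readers and writers.

#' Read a genome (or any FASTA) as a DNAStringSet
#'
#' Sequences are uppercased, U is converted to T and IUPAC ambiguity codes
#' are collapsed to N for search purposes (the original records are kept in
#' `metadata(x)$original`). Names are the first whitespace-delimited token.
#'
#' @param path FASTA file (plain text; CRLF accepted).
#' @return DNAStringSet.
#' @export
readGenome <- function(path) {
  x <- Biostrings::readBStringSet(path)   # tolerate U, lower case, CR
  if (!length(x)) stop("no sequences in ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicate sequence IDs in ", path)
  orig <- as.character(x)
  ch <- gsub("[\r ]", "", toupper(orig))
  if (any(nchar(ch) == 0)) stop("empty record in ", path)
  ch <- chartr("U", "T", ch)
  ch <- gsub("[^ACGTN]", "N", ch)
  out <- DNAStringSet(setNames(ch, names(x)))
  metadata(out)$original <- orig
  out
}

#' Read a consensus library FASTA
#'
#' Headers in the RepeatMasker style `name#Class/Superfamily` are parsed
#' into the classification columns.
#'
#' @param path FASTA file.
#' @return a [ConsensusLibrary-class].
#' @export
readConsensusLibrary <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("no sequences in ", path)
  ch <- gsub("[\r ]", "", toupper(as.character(x)))
  ch <- gsub("[^ACGTN]", "N", chartr("U", "T", ch))
  y <- DNAStringSet(setNames(ch, names(x)))
  if (anyDuplicated(sub("\\s.*$", "", sub("#.*$", "", names(y)))))
    stop("duplicate consensus IDs in ", path)
  ConsensusLibrary(y)
}

## classification path for FASTA headers
classPath <- function(info) {
  vapply(seq_len(nrow(info)), function(i) {
    cls <- info$class[i]
    if (cls == "LTR" && !is.na(info$superfamily[i]))
      paste0("LTR/", info$superfamily[i])
    else if (cls == "LINE/CR1") "LINE/CR1"
    else if (is.na(cls) || cls == "Unknown") "Unknown"
    else cls
  }, character(1))
}

#' Write a consensus library as FASTA with `name#Class/Superfamily` headers
#'
#' @param lib a [ConsensusLibrary-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeConsensusLibrary <- function(lib, path) {
  seqs <- consensusSeqs(lib)
  names(seqs) <- paste0(names(seqs), "#", classPath(consensusInfo(lib)))
  writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Write sequences as 60-column FASTA
#' @param x DNAStringSet (or named character).
#' @param path output file.
#' @export
writeFasta <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- DNAStringSet(x)
  writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Write genomic intervals as BED6
#'
#' Coordinates are converted from the internal 1-based closed convention to
#' BED's 0-based half-open; scores are clipped to 0-1000.
#'
#' @param gr GRanges with optional `name`/`query` and `score` columns.
#' @param path output file.
#' @param seqLengths optional named lengths; intervals outside bounds error.
#' @export
writeBed <- function(gr, path, seqLengths = NULL) {
  if (!is.null(seqLengths)) {
    sn <- as.character(seqnames(gr))
    if (any(IRanges::start(gr) < 1) ||
        any(IRanges::end(gr) > seqLengths[sn]))
      stop("interval outside sequence bounds")
  }
  m <- mcols(gr)
  nm <- if (!is.null(m$name)) m$name else if (!is.null(m$query)) m$query
    else rep(".", length(gr))
  sc <- if (!is.null(m$score)) pmax(0, pmin(1000, round(m$score)))
    else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), IRanges::start(gr) - 1L,
                   IRanges::end(gr), nm, sc, st)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file as GRanges (internal 1-based closed coordinates)
#' @param path BED file.
#' @return GRanges with `name` and `score` columns.
#' @export
readBed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("not a BED file: ", path)
  if (ncol(df) < 6) for (i in (ncol(df) + 1):6)
    df[[i]] <- switch(as.character(i), `4` = ".", `5` = 0, `6` = ".")
  str <- df[[6]]
  str[!str %in% c("+", "-")] <- "*"
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]), strand = str)
  mcols(gr) <- DataFrame(name = df[[4]], score = df[[5]])
  gr
}

#' Write genomic intervals as GFF3 (1-based closed)
#'
#' @param gr GRanges; `query` (or `name`) becomes the ID attribute and the
#'   classification is carried in a `class` attribute when present.
#' @param path output file.
#' @param type feature type (column 3).
#' @param source column 2 value.
#' @export
writeGff3 <- function(gr, path, type = "dispersed_repeat", source = "tecur") {
  m <- mcols(gr)
  nm <- if (!is.null(m$name)) m$name else if (!is.null(m$query)) m$query
    else paste0("feat", seq_along(gr))
  cls <- if (!is.null(m$class)) paste0(";class=", m$class) else ""
  sc <- if (!is.null(m$score)) m$score else "."
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\tID=%s%s",
                   as.character(seqnames(gr)), source, type,
                   IRanges::start(gr), IRanges::end(gr), as.character(sc),
                   st, nm, cls)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a mask track as .out-style TSV, alignment sidecar, .tbl and BED
#'
#' Produces `<prefix>.out.tsv` (score, %divergence, identity, target
#' interval, strand, subfamily, class), `<prefix>.align.tsv` (per-hit
#' alignment rows), `<prefix>.tbl.txt` (class summary in the
#' annotation-summary layout) and `<prefix>.bed`.
#'
#' @param track a [MaskTrack-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
writeMaskTrack <- function(track, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- maskHits(track)
  m <- mcols(h)
  cls <- hitClass(track)
  outPath <- file.path(dir, paste0(prefix, ".out.tsv"))
  alnPath <- file.path(dir, paste0(prefix, ".align.tsv"))
  tblPath <- file.path(dir, paste0(prefix, ".tbl.txt"))
  bedPath <- file.path(dir, paste0(prefix, ".bed"))
  out <- data.frame(score = m$score, div = round(100 * (1 - m$pid), 2),
                    target = as.character(seqnames(h)),
                    start = IRanges::start(h), end = IRanges::end(h),
                    strand = as.character(strand(h)), subfamily = m$query,
                    class = cls, qstart = m$qstart, qend = m$qend,
                    stringsAsFactors = FALSE)
  write.table(out, outPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(subfamily = m$query, aln_q = m$aln_q,
                         aln_t = m$aln_t, stringsAsFactors = FALSE),
              alnPath, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- summaryTable(track)
  writeLines(c(sprintf("total length: %d bp", as.integer(track@genomeLength)),
               sprintf("%-28s %8s %14s %8s", "type", "copies", "bp", "%"),
               sprintf("%-28s %8d %14d %8.2f", st$type, st$copies,
                       as.integer(st$bp), st$pct)), tblPath)
  writeBed(h, bedPath, seqLengths = track@seqLengths)
  invisible(c(outPath, alnPath, tblPath, bedPath))
}

#' Read a mask track written by [writeMaskTrack()]
#' @param dir directory; @param prefix prefix used at write time.
#' @param seqLengths named integer genome lengths.
#' @param library optional DataFrame with name/class columns; rebuilt from
#'   the .out file when omitted.
#' @return a [MaskTrack-class].
#' @export
readMaskTrack <- function(dir, prefix = "mask", seqLengths, library = NULL) {
  out <- read.table(file.path(dir, paste0(prefix, ".out.tsv")), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  aln <- read.table(file.path(dir, paste0(prefix, ".align.tsv")), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  gr <- GRanges(out$target, IRanges(out$start, out$end), strand = out$strand)
  mcols(gr) <- DataFrame(query = out$subfamily, qstart = out$qstart,
                         qend = out$qend, score = out$score,
                         pid = 1 - out$div / 100, evalue = NA_real_,
                         aln_q = aln$aln_q, aln_t = aln$aln_t)
  if (is.null(library)) {
    u <- !duplicated(out$subfamily)
    library <- DataFrame(name = out$subfamily[u], class = out$class[u],
                         superfamily = NA_character_,
                         family = out$subfamily[u], subfamily = out$subfamily[u])
  }
  new("MaskTrack", hits = gr, genomeLength = sum(as.numeric(seqLengths)),
      seqLengths = as.integer(seqLengths) |> setNames(names(seqLengths)),
      library = library)
}

#' Write a simulation: genome FASTA, truth library, ground-truth BED + JSON
#'
#' @param sim a [TESimulation-class].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gPath <- file.path(dir, "genome.fa")
  tPath <- file.path(dir, "truth.fa")
  bPath <- file.path(dir, "copies.bed")
  jPath <- file.path(dir, "copies.json")
  writeFasta(simGenome(sim), gPath)
  writeConsensusLibrary(simTruth(sim), tPath)
  cp <- simCopies(sim)
  m <- mcols(cp)
  gr <- granges(cp)
  mcols(gr) <- DataFrame(name = m$copy_id, score = 0L)
  writeBed(gr, bPath)
  jsonlite::write_json(
    data.frame(copy_id = m$copy_id, family = m$family,
               structure = m$structure, tsd = m$tsd,
               tsd_length = m$tsd_length,
               nominal_divergence = m$nominal_divergence,
               realized_divergence = m$realized_divergence,
               stringsAsFactors = FALSE),
    jPath, digits = NA)
  invisible(c(gPath, tPath, bPath, jPath))
}

#' Read a species tree (Newick)
#' @param x file path, Newick string or phylo object.
#' @return an `ape::phylo`.
#' @export
readSpeciesTree <- function(x) asPhylo(x)
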