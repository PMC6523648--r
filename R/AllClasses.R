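#' ConsensusLibrary: a set of TE consensus sequences with classification
#'
#' Holds curated or predicted TE consensus sequences together with their
#' classification (element class, ERV superfamily, family, subfamily), the
#' boundary metadata used for classification (TSD length(s), terminal motifs)
#' and provenance. The sequence container is a [Biostrings::DNAStringSet];
#' the per-consensus annotation is a [S4Vectors::DataFrame] with one row per
#' sequence.
#'
#' Annotation columns always present: `name`, `class` (one of `"LTR"`,
#' `"LINE/CR1"`, `"SINE"`, `"DNA"`, `"Unknown"`), `superfamily` (`"ERV1"`,
#' `"ERV2"`, `"ERV3"` or `NA`), `family`, `subfamily`, `tsd_length`
#' (`IntegerList`-like comma string, 0/empty if n/a), `end5`, `end3`
#' (terminal dinucleotides for LTR elements), `cr1_motif_pos` (1-based start
#' of the 3' octamer for CR1, NA otherwise), `source` (free-text provenance),
#' `n_hits` (hits used during curation, NA if not curated).
#'
#' @slot seqs DNAStringSet of consensus sequences (names = `name` column).
#' @slot info DataFrame of per-consensus annotation.
#' @export
setClass("ConsensusLibrary",
  representation(seqs = "DNAStringSet", info = "DataFrame"),
  validity = function(object) {
    msg <- NULL
    if (length(object@seqs) != nrow(object@info))
      msg <- c(msg, "seqs and info must have the same length")
    if (anyDuplicated(names(object@seqs)))
      msg <- c(msg, "consensus names must be unique")
    if (!all(c("name", "class", "superfamily", "family", "subfamily") %in%
             colnames(object@info)))
      msg <- c(msg, "info is missing mandatory columns")
    if (length(object@seqs) &&
        !identical(as.character(object@info$name), names(object@seqs)))
      msg <- c(msg, "info$name must match names(seqs)")
    if (is.null(msg)) TRUE else msg
  })

#' MaskTrack: a resolved set of homology hits on one genome
#'
#' The result of masking a genome with a consensus library: hits that survived
#' overlap resolution, as a [GenomicRanges::GRanges] on the genome with
#' metadata columns `query` (consensus name), `qstart`/`qend` (consensus
#' interval, 1-based closed, forward consensus orientation), `score`, `pid`
#' (identity over aligned non-gap columns), `evalue`, and the per-hit gapped
#' alignment rows `aln_q` (consensus) and `aln_t` (genomic copy, in consensus
#' orientation). Overlapping lower-scoring hits have been trimmed, so hit
#' intervals are disjoint per sequence.
#'
#' @slot hits GRanges of resolved hits.
#' @slot genomeLength total genome length in bp.
#' @slot seqLengths named integer vector of per-sequence lengths.
#' @slot library DataFrame mapping consensus name to class/superfamily/family.
#' @export
setClass("MaskTrack",
  representation(hits = "GRanges", genomeLength = "numeric",
                 seqLengths = "integer", library = "DataFrame"),
  validity = function(object) {
    msg <- NULL
    if (object@genomeLength <= 0) msg <- c(msg, "genomeLength must be > 0")
    h <- object@hits
    if (length(h)) {
      sp <- split(IRanges::ranges(h), as.character(GenomicRanges::seqnames(h)))
      ov <- vapply(sp, function(r)
        sum(IRanges::width(IRanges::reduce(r))) != sum(IRanges::width(r)),
        logical(1))
      if (any(ov)) msg <- c(msg, "resolved hits must not overlap")
    }
    if (is.null(msg)) TRUE else msg
  })

#' TESimulation: a simulated genome plus its ground truth
#'
#' @slot genome DNAStringSet, the simulated genome.
#' @slot truth ConsensusLibrary of the ancestral ("truth") consensus sequences.
#' @slot copies GRanges of every inserted copy with metadata columns `family`,
#'   `structure` (`"full_length"`, `"solo_LTR"`, `"truncated"`), `tsd`
#'   (duplicated target-site sequence, "" if none), `tsd_length`,
#'   `nominal_divergence`, `realized_divergence` (substituted fraction of the
#'   inserted copy relative to its ancestral sequence), `copy_id`.
#'   Coordinates are the element interval excluding the TSDs.
#' @slot config the `simConfig()` list used.
#' @export
setClass("TESimulation",
  representation(genome = "DNAStringSet", truth = "ConsensusLibrary",
                 copies = "GRanges", config = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@copies)) {
      sl <- setNames(BiocGenerics::width(object@genome), names(object@genome))
      cs <- as.character(GenomicRanges::seqnames(object@copies))
      if (!all(cs %in% names(sl)))
        msg <- c(msg, "copies must lie on simulated sequences")
      else if (any(IRanges::start(object@copies) < 1) ||
               any(IRanges::end(object@copies) > sl[cs]))
        msg <- c(msg, "copy intervals exceed genome bounds")
    }
    if (is.null(msg)) TRUE else msg
  })

#' CurationAlignment: hit rows anchored on a seed consensus
#'
#' A multiple alignment of flanked hits used during curation. Columns are
#' positions in a coordinate frame centred on the seed consensus: column
#' `c` corresponds to consensus position `c - offset`, so columns
#' `1..offset` are 5'-flank space and columns beyond `offset + width(seed)`
#' are 3'-flank space. `mat[r, c]` holds the character of row `r` ('.'
#' where the row has no sequence); `isCore[r, c]` is TRUE where the
#' character was placed by the row's hit alignment (or promoted during
#' boundary extension) rather than being unaligned flank.
#'
#' @slot mat character matrix (rows = flanked hits).
#' @slot isCore logical matrix, same dimensions.
#' @slot offset integer; column of consensus position 1 minus 1.
#' @slot consensusName name of the seed consensus.
#' @slot hits GRanges of the underlying hits (one per row).
#' @export
setClass("CurationAlignment",
  representation(mat = "matrix", isCore = "matrix", offset = "integer",
                 consensusName = "character", hits = "GRanges"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@mat), dim(object@isCore)))
      msg <- c(msg, "mat and isCore dimensions differ")
    if (nrow(object@mat) < 2) msg <- c(msg, "alignment needs >= 2 rows")
    if (is.null(msg)) TRUE else msg
  })

## ---- constructors and accessors ----

#' Create a ConsensusLibrary
#'
#' @param seqs DNAStringSet (or named character vector) of consensus sequences.
#' @param info optional DataFrame/data.frame of annotation; missing mandatory
#'   columns are filled with defaults parsed from `name#Class/Superfamily`
#'   style names when present.
#' @return A [ConsensusLibrary-class] object.
#' @export
ConsensusLibrary <- function(seqs, info = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(unlist(seqs))
  nm <- names(seqs)
  if (is.null(nm)) stop("consensus sequences must be named")
  parsed <- parseRmHeaders(nm)
  names(seqs) <- parsed$name
  if (is.null(info)) info <- parsed else {
    info <- DataFrame(info)
    for (col in colnames(parsed)) if (is.null(info[[col]])) info[[col]] <- parsed[[col]]
  }
  for (col in c("tsd_length", "end5", "end3", "cr1_motif_pos", "source", "n_hits"))
    if (is.null(info[[col]]))
      info[[col]] <- if (col %in% c("cr1_motif_pos", "n_hits")) NA_integer_ else NA_character_
  rownames(info) <- NULL
  new("ConsensusLibrary", seqs = seqs, info = DataFrame(info))
}

## Parse RepeatMasker-style "name#Class/Superfamily" headers.
parseRmHeaders <- function(nm) {
  nm <- sub("\\s.*$", "", nm)
  has <- grepl("#", nm, fixed = TRUE)
  name <- ifelse(has, sub("#.*$", "", nm), nm)
  path <- ifelse(has, sub("^[^#]*#", "", nm), "Unknown")
  cls <- sub("/.*$", "", path)
  sup <- ifelse(grepl("/", path), sub("^[^/]*/", "", path), NA_character_)
  cls[cls %in% c("LINE")] <- ifelse(!is.na(sup[cls %in% c("LINE")]) &
                                      sup[cls %in% c("LINE")] == "CR1",
                                    "LINE/CR1", "LINE/CR1")
  cls[!cls %in% c("LTR", "LINE/CR1", "SINE", "DNA")] <- "Unknown"
  superfam <- ifelse(!is.na(sup) & sup %in% c("ERV1", "ERV2", "ERV3"), sup, NA_character_)
  DataFrame(name = name, class = cls, superfamily = superfam,
            family = name, subfamily = name)
}

#' @describeIn ConsensusLibrary sequences accessor
#' @param x,object a ConsensusLibrary.
#' @export
consensusSeqs <- function(x) x@seqs

#' @describeIn ConsensusLibrary annotation accessor
#' @export
consensusInfo <- function(x) x@info

#' @export
setMethod("length", "ConsensusLibrary", function(x) length(x@seqs))

#' @export
setMethod("names", "ConsensusLibrary", function(x) names(x@seqs))

#' @export
setMethod("[", "ConsensusLibrary", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("ConsensusLibrary", seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

#' @export
setMethod("show", "ConsensusLibrary", function(object) {
  cat("ConsensusLibrary with", length(object), "consensus sequence(s)\n")
  if (length(object)) {
    tab <- table(object@info$class)
    cat(" classes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    cat(" lengths:", min(BiocGenerics::width(object@seqs)), "-",
        max(BiocGenerics::width(object@seqs)), "bp\n")
  }
})

#' Combine consensus libraries
#' @param x,... ConsensusLibrary objects.
#' @export
setMethod("c", "ConsensusLibrary", function(x, ...) {
  libs <- c(list(x), list(...))
  seqs <- do.call(c, lapply(libs, consensusSeqs))
  info <- do.call(rbind, lapply(libs, consensusInfo))
  new("ConsensusLibrary", seqs = seqs, info = info)
})

#' MaskTrack accessors
#'
#' `maskHits()` returns the resolved hit GRanges; `genomeLength()` the total
#' genome size used for densities; `classTotals()` per-class copy and bp
#' totals.
#' @param x a MaskTrack.
#' @export
maskHits <- function(x) x@hits

#' @rdname maskHits
#' @export
genomeLength <- function(x) x@genomeLength

#' @rdname maskHits
#' @export
classTotals <- function(x) {
  h <- x@hits
  cls <- hitClass(x)
  df <- data.frame(class = cls, bp = if (length(h)) IRanges::width(h) else integer(0))
  agg <- stats::aggregate(bp ~ class, data = df, FUN = sum)
  cnt <- as.data.frame(table(df$class), stringsAsFactors = FALSE)
  names(cnt) <- c("class", "copies")
  out <- merge(cnt, agg, by = "class", all = TRUE)
  out$bp[is.na(out$bp)] <- 0
  out
}

## class of each hit, from the track's library table
hitClass <- function(x) {
  lib <- x@library
  idx <- match(mcols(x@hits)$query, lib$name)
  cls <- as.character(lib$class[idx])
  cls[is.na(cls)] <- "Unknown"
  cls
}

#' @export
setMethod("show", "MaskTrack", function(object) {
  cat("MaskTrack:", length(object@hits), "resolved hit(s) on",
      length(object@seqLengths), "sequence(s) (", object@genomeLength, "bp )\n")
  if (length(object@hits)) {
    ct <- classTotals(object)
    for (i in seq_len(nrow(ct)))
      cat(sprintf("  %-10s %6d copies %10d bp (%.2f%%)\n", ct$class[i],
                  ct$copies[i], ct$bp[i], 100 * ct$bp[i] / object@genomeLength))
  }
})

#' TESimulation accessors
#' @param x a TESimulation.
#' @export
simGenome <- function(x) x@genome

#' @rdname simGenome
#' @export
simTruth <- function(x) x@truth

#' @rdname simGenome
#' @export
simCopies <- function(x) x@copies

#' @rdname simGenome
#' @export
simConfigOf <- function(x) x@config

#' @export
setMethod("show", "TESimulation", function(object) {
  cat("TESimulation:", length(object@genome), "sequence(s),",
      sum(BiocGenerics::width(object@genome)), "bp;",
      length(object@copies), "inserted TE copies from",
      length(object@truth), "families\n")
  if (length(object@copies)) {
    st <- table(mcols(object@copies)$structure)
    cat(" structures:", paste(names(st), st, sep = ":", collapse = " "), "\n")
  }
})

#' @export
setMethod("show", "CurationAlignment", function(object) {
  cat("CurationAlignment for", object@consensusName, ":",
      nrow(object@mat), "rows x", ncol(object@mat), "columns\n")
})
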