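## Superfamily, family and subfamily assignment and naming.

#' ERV superfamily from TSD length(s)
#'
#' A 4-bp target site duplication diagnoses superfamily ERV1, 6 bp ERV2
#' (K/2) and 5 bp ERV3 (L/3). Multiple supported lengths yield an
#' "ambiguous" call with the lengths recorded; an empty set is "unknown".
#'
#' @param tsdLengths integer vector of supported TSD lengths.
#' @return list: `superfamily` (character or NA), `status` ("ok",
#'   "ambiguous", "unknown"), `lengths`, `note`.
#' @export
superfamilyFromTSD <- function(tsdLengths) {
  tsdLengths <- sort(unique(as.integer(tsdLengths)))
  known <- tsdLengths[tsdLengths %in% 4:6]
  note <- if (length(setdiff(tsdLengths, 4:6)))
    paste("lengths outside 4-6 ignored:",
          paste(setdiff(tsdLengths, 4:6), collapse = ",")) else NA_character_
  if (!length(known))
    return(list(superfamily = NA_character_, status = "unknown",
                lengths = tsdLengths, note = note))
  if (length(known) > 1)
    return(list(superfamily = NA_character_, status = "ambiguous",
                lengths = known, note = note))
  map <- c(`4` = "ERV1", `5` = "ERV3", `6` = "ERV2")
  list(superfamily = unname(map[as.character(known)]), status = "ok",
       lengths = known, note = note)
}

## directional 80-80-80 support of query against subject
.familySupport <- function(q, s, minIdentity, k) {
  hits <- seedExtendSearch(q, DNAStringSet(c(subject = s)), k = k,
                           minScore = 40, queryName = "q")
  if (!length(hits)) return(NULL)
  good <- hits[mcols(hits)$pid > minIdentity]
  if (!length(good)) return(list(identity = max(mcols(hits)$pid),
                                 coverage = 0, alignedBp = 0))
  shortLen <- min(nchar(q), nchar(s))
  iv <- if (nchar(q) <= nchar(s))
    IRanges(mcols(good)$qstart, mcols(good)$qend)
  else IRanges(IRanges::start(good), IRanges::end(good))
  covBp <- sum(IRanges::width(IRanges::reduce(iv)))
  list(identity = max(mcols(good)$pid), coverage = covBp / shortLen,
       alignedBp = covBp)
}

#' Are two consensuses the same TE family? (80-80-80 rule)
#'
#' Two elements belong to one family when local alignments with more than
#' 80% identity cover more than 80% of the shorter consensus and total at
#' least 80 aligned bp. Both directions are evaluated and the better
#' support is used, so the decision is symmetric.
#'
#' @param a,b consensus sequences (character/DNAString).
#' @param minIdentity,minCoverage,minLength the three 80-80-80 thresholds.
#' @param k seed length for the underlying search.
#' @return list: `same` (logical), `identity`, `coverage`, `alignedBp`.
#' @export
sameFamily <- function(a, b, minIdentity = 0.80, minCoverage = 0.80,
                       minLength = 80, k = 11) {
  a <- as.character(a); b <- as.character(b)
  s1 <- .familySupport(a, b, minIdentity, k)
  s2 <- .familySupport(b, a, minIdentity, k)
  best <- NULL
  for (s in list(s1, s2)) {
    if (is.null(s)) next
    if (is.null(best) || s$coverage > best$coverage) best <- s
  }
  if (is.null(best))
    return(list(same = FALSE, identity = 0, coverage = 0, alignedBp = 0))
  best$same <- best$coverage > minCoverage && best$alignedBp >= minLength
  best[c("same", "identity", "coverage", "alignedBp")]
}

#' Assign novel consensuses to existing or new families
#'
#' Each novel consensus is tested against the reference library first and
#' then against already-accepted novel families (novel elements are checked
#' against each other); candidate matches are ranked by descending support
#' identity and the first qualifying match wins. Unmatched consensuses
#' found a new family.
#'
#' @param novel [ConsensusLibrary-class] of curated consensuses.
#' @param reference optional [ConsensusLibrary-class] of known families.
#' @param ... thresholds passed to [sameFamily()].
#' @return data.frame with columns `name`, `decision`
#'   ("existing_family"/"new_family"), `family`, `matched_library`
#'   ("reference"/"within-batch"/NA), `identity`, `coverage`, `aligned_bp`.
#' @export
assignFamilies <- function(novel, reference = NULL, ...) {
  refSeqs <- if (!is.null(reference) && length(reference))
    as.character(consensusSeqs(reference)) else character(0)
  refFam <- if (length(refSeqs)) as.character(consensusInfo(reference)$family)
    else character(0)
  accSeqs <- character(0); accFam <- character(0)
  out <- list()
  for (i in seq_len(length(novel))) {
    nm <- names(novel)[i]
    q <- as.character(consensusSeqs(novel)[[i]])
    cand <- data.frame(seq = c(refSeqs, accSeqs),
                       fam = c(refFam, accFam),
                       lib = rep(c("reference", "within-batch"),
                                 c(length(refSeqs), length(accSeqs))),
                       stringsAsFactors = FALSE)
    hit <- NULL
    if (nrow(cand)) {
      sup <- lapply(cand$seq, function(s) sameFamily(q, s, ...))
      okIdx <- which(vapply(sup, `[[`, logical(1), "same"))
      if (length(okIdx)) {
        best <- okIdx[order(-vapply(sup[okIdx], `[[`, numeric(1), "identity"))][1]
        hit <- c(cand[best, c("fam", "lib")], sup[[best]])
      }
    }
    if (is.null(hit)) {
      out[[nm]] <- data.frame(name = nm, decision = "new_family", family = nm,
                              matched_library = NA_character_, identity = NA,
                              coverage = NA, aligned_bp = NA,
                              stringsAsFactors = FALSE)
      accSeqs <- c(accSeqs, q); accFam <- c(accFam, nm)
    } else {
      out[[nm]] <- data.frame(name = nm, decision = "existing_family",
                              family = hit$fam, matched_library = hit$lib,
                              identity = hit$identity, coverage = hit$coverage,
                              aligned_bp = hit$alignedBp,
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Global alignment identity of two sequences (gaps count as mismatches)
#'
#' @param a,b sequences.
#' @return matches / alignment length.
#' @export
globalIdentity <- function(a, b) {
  pa <- pairwiseAlignment(DNAString(as.character(a)), DNAString(as.character(b)),
                          type = "global", substitutionMatrix = .tecurSubMat(),
                          gapOpening = 5, gapExtension = 2)
  x <- chars(as.character(alignedPattern(pa)))
  y <- chars(as.character(alignedSubject(pa)))
  sum(x == y & x != "-") / length(x)
}

#' Split family members into subfamilies at 95% identity
#'
#' Members whose consensus sequences are less than `threshold` (95%) similar
#' at the nucleotide level (global alignment, gaps as mismatches) belong to
#' separate subfamilies. Clustering is single linkage: a member joins a
#' subfamily when it is >= threshold similar to any member of it.
#'
#' @param members [ConsensusLibrary-class] or named character vector of
#'   same-family consensuses.
#' @param threshold identity at or above which two members share a subfamily.
#' @return integer vector of cluster ids (named by member), numbered by
#'   first appearance.
#' @export
splitSubfamilies <- function(members, threshold = 0.95) {
  seqs <- if (is(members, "ConsensusLibrary"))
    as.character(consensusSeqs(members)) else as.character(members)
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("m", seq_len(n))
  if (n == 1) return(setNames(1L, names(seqs)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (globalIdentity(seqs[[i]], seqs[[j]]) >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  setNames(ids, names(seqs))
}

#' Name a new family or a heterospecific subfamily
#'
#' New families curated from a species get `<speciesCode>LTR<letter><n>`
#' names where the letter encodes the ERV superfamily (ERV2 -> "K",
#' ERV3 -> "L", ERV1 -> no letter), e.g. `UcyLTRK7`; CR1 families get
#' `<speciesCode>CR1_<n>`. A subfamily that belongs to a family first
#' described in another species is named `<family>_<speciesCode>`, e.g.
#' `TguERVL2_I_Ucy`. Counters are explicit so naming is deterministic.
#'
#' @param speciesCode short species code, e.g. "Ucy".
#' @param superfamily "ERV1"/"ERV2"/"ERV3"/NA, for new LTR families.
#' @param family existing family name for heterospecific membership; NULL
#'   for a new family.
#' @param elementClass "LTR" or "LINE/CR1" (new families only).
#' @param counters named integer list from a previous call (or empty list).
#' @return list: `name`, `counters` (updated). Errors on a name collision.
#' @export
nameSubfamily <- function(speciesCode, superfamily = NA, family = NULL,
                          elementClass = "LTR", counters = list()) {
  used <- counters$.used
  if (is.null(used)) used <- character(0)
  if (!is.null(family)) {
    nm <- paste0(family, "_", speciesCode)
  } else if (elementClass == "LINE/CR1") {
    key <- "CR1"
    counters[[key]] <- (counters[[key]] %||% 0L) + 1L
    nm <- paste0(speciesCode, "CR1_", counters[[key]])
  } else {
    letter <- switch(ifelse(is.na(superfamily), "NA", superfamily),
                     ERV1 = "", ERV2 = "K", ERV3 = "L", "X")
    key <- paste0("LTR", letter)
    counters[[key]] <- (counters[[key]] %||% 0L) + 1L
    nm <- paste0(speciesCode, "LTR", letter, counters[[key]])
  }
  if (nm %in% used) stop("name collision: ", nm)
  counters$.used <- c(used, nm)
  list(name = nm, counters = counters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify and name a curated library
#'
#' Full classification driver: assigns each curated consensus to an existing
#' or new family ([assignFamilies()]), splits each family into subfamilies
#' at 95% identity ([splitSubfamilies()]) and applies the naming convention
#' ([nameSubfamily()]). ERV superfamilies are taken from the TSD-based calls
#' stored in the library annotation.
#'
#' @param curated [ConsensusLibrary-class] from [curateLibrary()].
#' @param reference optional [ConsensusLibrary-class] of known families.
#' @param speciesCode species code used in names.
#' @param threshold subfamily identity threshold.
#' @return list: `library` (renamed/annotated [ConsensusLibrary-class]),
#'   `assignments` (family decisions), `subfamilies` (member -> subfamily
#'   name map).
#' @export
classifyLibrary <- function(curated, reference = NULL, speciesCode = "Ucy",
                            threshold = 0.95) {
  asg <- assignFamilies(curated, reference)
  info <- consensusInfo(curated)
  counters <- list()
  famName <- setNames(character(nrow(asg)), asg$name)
  subName <- setNames(character(nrow(asg)), asg$name)
  for (fam in unique(asg$family)) {
    members <- asg$name[asg$family == fam]
    fromRef <- any(asg$decision[asg$family == fam] == "existing_family" &
                     asg$matched_library[asg$family == fam] == "reference")
    i1 <- members[1]
    sup <- info$superfamily[match(i1, info$name)]
    cls <- info$class[match(i1, info$name)]
    if (fromRef) {
      base <- fam
      famName[members] <- fam
    } else {
      nn <- nameSubfamily(speciesCode, superfamily = sup,
                          elementClass = cls, counters = counters)
      counters <- nn$counters
      base <- nn$name
      famName[members] <- base
    }
    cl <- splitSubfamilies(curated[members], threshold = threshold)
    for (m in members) {
      id <- cl[[m]]
      subName[m] <- if (fromRef) paste0(base, "_", speciesCode,
                                        if (id > 1) letters[id] else "")
      else paste0(base, if (id > 1) letters[id] else "")
    }
  }
  lib <- curated
  lib@info$family <- unname(famName[lib@info$name])
  lib@info$subfamily <- unname(subName[lib@info$name])
  out <- setNames(consensusSeqs(lib), unname(subName[lib@info$name]))
  lib@seqs <- out
  lib@info$name <- names(out)
  list(library = lib, assignments = asg,
       subfamilies = data.frame(member = names(subName),
                                family = unname(famName),
                                subfamily = unname(subName),
                                stringsAsFactors = FALSE))
}
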