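## Synthetic genome simulator: TE insertions with ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic genome generator. The mutational model is a
#' per-site substitution model with a transition/transversion rate ratio
#' (`kappa`), multiplicative transition acceleration at CpG dinucleotides
#' (`cpgMultiplier`) and an optional APOBEC-like G-to-A editing step applied
#' to the element's sense strand (`apobecRate`). There is no indel model.
#'
#' @param genomeLength background genome length in bp (before insertions).
#' @param gcContent background GC fraction in (0, 1).
#' @param seed integer seed; all randomness in the simulator derives from it.
#' @param families list of [familySpec()] objects.
#' @param kappa transition/transversion rate ratio (alpha/beta), default 2.
#' @param cpgMultiplier fold-increase of the transition rate at CpG sites.
#' @param apobecRate per-G probability of a G-to-A edit on the sense strand.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(genomeLength = 5e6, gcContent = 0.42, seed = 1,
                      families = list(), kappa = 2, cpgMultiplier = 10,
                      apobecRate = 0) {
  stopifnot(genomeLength > 0, gcContent > 0, gcContent < 1,
            cpgMultiplier >= 1, kappa > 0,
            apobecRate >= 0, apobecRate <= 1)
  if (length(families) && is.null(names(families)))
    names(families) <- vapply(families, `[[`, character(1), "name")
  cfg <- list(genomeLength = genomeLength, gcContent = gcContent,
              seed = as.integer(seed), families = families, kappa = kappa,
              cpgMultiplier = cpgMultiplier, apobecRate = apobecRate)
  class(cfg) <- "simConfig"
  cfg
}

#' TE family specification for the simulator
#'
#' ERV families are structured LTR-internal-LTR with identical LTRs starting
#' `TG` and ending `CA`, and insert with a 4/5/6-bp target site duplication
#' (TSD); a fraction `soloLtrProb` of copies is reduced to a solo-LTR (one
#' LTR plus both TSDs), emulating within-element non-allelic homologous
#' recombination. CR1 families carry the 3'-terminal octamer `ATTCTRTG` and
#' copies are 5'-truncated by a geometric draw. SINEs insert full-length.
#'
#' @param name family name.
#' @param class one of "ERV", "CR1", "SINE".
#' @param ltrLength,internalLength ERV geometry in bp.
#' @param totalLength CR1/SINE consensus length in bp.
#' @param tsdLength TSD length(s); subset of 4/5/6 for ERV (a vector yields a
#'   mixed-TSD family, each copy drawing one length), 0 otherwise.
#' @param copyNumber number of copies to insert.
#' @param divergence per-site expected substitution rate per copy; a vector
#'   is recycled across copies (multiple insertion bursts).
#' @param soloLtrProb fraction of ERV copies reduced to solo-LTRs; applied as
#'   an exact fraction (`round(soloLtrProb * copyNumber)` copies).
#' @param cr1TruncationMean mean 5' truncation in bp (geometric law), CR1 only.
#' @return a list of class `familySpec`.
#' @export
familySpec <- function(name, class = c("ERV", "CR1", "SINE"),
                       ltrLength = NULL, internalLength = NULL,
                       totalLength = NULL, tsdLength = NULL,
                       copyNumber = 10, divergence = 0.05,
                       soloLtrProb = 0, cr1TruncationMean = NULL) {
  class <- match.arg(class)
  stopifnot(copyNumber >= 0, all(divergence >= 0),
            soloLtrProb >= 0, soloLtrProb <= 1)
  if (class == "ERV") {
    stopifnot(!is.null(ltrLength), !is.null(internalLength))
    if (ltrLength < 8) stop("ltrLength must be >= 8 to carry TG...CA ends")
    if (is.null(tsdLength)) tsdLength <- 6L
    if (!all(tsdLength %in% 4:6)) stop("ERV tsdLength must be in {4,5,6}")
  } else {
    stopifnot(!is.null(totalLength))
    if (totalLength < 8) stop("totalLength must be >= 8")
    tsdLength <- 0L
    if (class == "CR1" && is.null(cr1TruncationMean)) cr1TruncationMean <- 1000
  }
  structure(list(name = name, class = class, ltrLength = ltrLength,
                 internalLength = internalLength, totalLength = totalLength,
                 tsdLength = as.integer(tsdLength), copyNumber = copyNumber,
                 divergence = divergence, soloLtrProb = soloLtrProb,
                 cr1TruncationMean = cr1TruncationMean),
            class = "familySpec")
}

## truth consensus sequences; consumes the current RNG stream
.truthLib <- function(config) {
  seqs <- character(0); cls <- character(0); sup <- character(0)
  for (fam in config$families) {
    if (fam$class == "ERV") {
      ltr <- chars(randomSeq(fam$ltrLength, config$gcContent))
      ltr[1:2] <- c("T", "G")
      ltr[(fam$ltrLength - 1):fam$ltrLength] <- c("C", "A")
      ltr <- paste(ltr, collapse = "")
      cons <- paste0(ltr, randomSeq(fam$internalLength, config$gcContent), ltr)
      cls <- c(cls, "LTR")
      sup <- c(sup, if (length(fam$tsdLength) == 1)
        c(`4` = "ERV1", `5` = "ERV3", `6` = "ERV2")[as.character(fam$tsdLength)]
        else NA_character_)
    } else if (fam$class == "CR1") {
      s <- chars(randomSeq(fam$totalLength, config$gcContent))
      r <- sample(c("A", "G"), 1)
      s[(fam$totalLength - 7):fam$totalLength] <-
        c("A", "T", "T", "C", "T", r, "T", "G")
      cons <- paste(s, collapse = "")
      cls <- c(cls, "LINE/CR1"); sup <- c(sup, NA_character_)
    } else {
      cons <- randomSeq(fam$totalLength, config$gcContent)
      cls <- c(cls, "SINE"); sup <- c(sup, NA_character_)
    }
    seqs[fam$name] <- cons
  }
  info <- DataFrame(name = names(seqs), class = cls, superfamily = sup,
                    family = names(seqs), subfamily = names(seqs),
                    tsd_length = vapply(config$families, function(f)
                      paste(f$tsdLength, collapse = ","), character(1)),
                    ltr_length = vapply(config$families, function(f)
                      ifelse(is.null(f$ltrLength), NA_integer_,
                             as.integer(f$ltrLength)), integer(1)),
                    source = "simulated truth")
  ConsensusLibrary(DNAStringSet(seqs), info)
}

#' Build the truth consensus library for a simulation
#'
#' Deterministic given `config$seed`: one consensus per family, with the
#' structural invariants enforced (identical ERV LTRs with `TG...CA` ends,
#' CR1 3'-terminal `ATTCTRTG`).
#'
#' @param config a [simConfig()].
#' @return a [ConsensusLibrary-class].
#' @export
makeTruthLibrary <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  .truthLib(config)
}

#' Mutate a sequence under the simulator's substitution model
#'
#' Substitutions are drawn independently per site. With divergence `d` and
#' ratio `kappa`, the per-site transition probability is
#' `d * kappa / (kappa + 2)` and each of the two transversions has
#' probability `d / (kappa + 2)` (so the expected substituted fraction is
#' `d`). At CpG dinucleotides (both positions), the transition probability is
#' multiplied by `cpgMultiplier` and capped so the total stays at most 1.
#' Finally, every remaining G on the sense strand is edited to A with
#' probability `config$apobecRate`. No indels are introduced.
#'
#' @param seq character string or DNAString.
#' @param divergence per-site expected substitution rate (>= 0).
#' @param config a [simConfig()] (supplies kappa, cpgMultiplier, apobecRate).
#' @return mutated sequence as a character string.
#' @export
evolveCopy <- function(seq, divergence, config) {
  stopifnot(divergence >= 0)
  x <- chars(as.character(seq))
  L <- length(x)
  if (!L) return("")
  kappa <- config$kappa
  alpha <- divergence * kappa / (kappa + 2)
  beta <- divergence / (kappa + 2)
  cpg <- rep(FALSE, L)
  if (L > 1) {
    i <- which(x[-L] == "C" & x[-1] == "G")
    cpg[i] <- TRUE; cpg[i + 1] <- TRUE
  }
  pts <- ifelse(cpg, pmin(alpha * config$cpgMultiplier, 1 - 2 * beta), alpha)
  u <- runif(L)
  ts <- u < pts
  tv1 <- !ts & u < pts + beta
  tv2 <- !ts & !tv1 & u < pts + 2 * beta
  tsMap <- c(A = "G", G = "A", C = "T", T = "C")
  tv1Map <- c(A = "C", C = "A", G = "C", T = "A")
  tv2Map <- c(A = "T", C = "G", G = "T", T = "G")
  known <- x %in% BASES
  x[ts & known] <- tsMap[x[ts & known]]
  x[tv1 & known] <- tv1Map[x[tv1 & known]]
  x[tv2 & known] <- tv2Map[x[tv2 & known]]
  if (config$apobecRate > 0) {
    g <- which(x == "G")
    if (length(g)) {
      hit <- g[runif(length(g)) < config$apobecRate]
      x[hit] <- "A"
    }
  }
  paste(x, collapse = "")
}

## fraction of differing sites between two equal-length strings
substFraction <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  mean(ca != cb)
}

#' Simulate a genome with TE insertions and ground truth
#'
#' Generates a neutral background sequence (resampled wherever it shares an
#' exact 30-mer with a truth consensus), then inserts every planned copy
#' sequentially at distinct positions. ERV copies are flanked by an exact
#' duplication of the target site (TSD); solo-LTR copies carry one evolved
#' LTR plus both TSDs; CR1 copies lose a geometric-law 5' segment (the 3'
#' end is always retained). Each copy is passed through [evolveCopy()] and
#' recorded in the ground truth with its realized divergence.
#'
#' @param config a [simConfig()].
#' @param truth optionally, a pre-built truth library (used by
#'   [simulateClade()] so all genomes share ancestral sequences). When NULL,
#'   the library is built from `config`.
#' @return a [TESimulation-class].
#' @export
simulateGenome <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  if (is.null(truth)) truth <- .truthLib(config)
  tseq <- as.character(consensusSeqs(truth))

  ## per-copy plan
  plan <- list()
  for (fam in config$families) {
    n <- fam$copyNumber
    if (!n) next
    div <- rep(fam$divergence, length.out = n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    structure_ <- rep("full_length", n)
    trunc <- integer(n)
    tsd <- integer(n)
    cons <- tseq[[fam$name]]
    if (fam$class == "ERV") {
      nSolo <- round(fam$soloLtrProb * n)
      if (nSolo) structure_[sample.int(n, nSolo)] <- "solo_LTR"
      tsd <- fam$tsdLength[sample.int(length(fam$tsdLength), n, replace = TRUE)]
    } else if (fam$class == "CR1") {
      L <- nchar(cons)
      trunc <- pmin(rgeom(n, 1 / (1 + fam$cr1TruncationMean)), max(L - 200, 0))
      structure_[trunc > 0] <- "truncated"
    }
    plan[[fam$name]] <- data.frame(
      family = fam$name, class = fam$class, idx = seq_len(n),
      structure = structure_, trunc = trunc, tsd_length = tsd,
      nominal = div, strand = strand, stringsAsFactors = FALSE)
  }
  plan <- if (length(plan)) do.call(rbind, plan) else
    data.frame(family = character(0), class = character(0), idx = integer(0),
               structure = character(0), trunc = integer(0),
               tsd_length = integer(0), nominal = numeric(0),
               strand = character(0))
  nTotal <- nrow(plan)

  ## source and evolved sequence per copy
  srcSeq <- character(nTotal); evSeq <- character(nTotal)
  realized <- numeric(nTotal)
  famSpecs <- config$families
  for (i in seq_len(nTotal)) {
    fam <- famSpecs[[plan$family[i]]]
    cons <- tseq[[fam$name]]
    src <- if (plan$structure[i] == "solo_LTR")
      substr(cons, 1, fam$ltrLength)
    else if (plan$class[i] == "CR1" && plan$trunc[i] > 0)
      substr(cons, plan$trunc[i] + 1, nchar(cons))
    else cons
    ev <- evolveCopy(src, plan$nominal[i], config)
    srcSeq[i] <- src; evSeq[i] <- ev
    realized[i] <- substFraction(src, ev)
  }
  insSeq <- ifelse(plan$strand == "-", revcompChr(evSeq), evSeq)
  insLen <- nchar(insSeq)
  if (nTotal && sum(insLen) >= config$genomeLength / 2)
    stop("total inserted bp must stay below half the background length")

  ## background, scrubbed of exact 30-mers shared with any truth consensus
  bg <- randomSeq(config$genomeLength, config$gcContent)
  bg <- scrubBackground(bg, tseq, config$gcContent)

  ## distinct, well-separated insertion points: jittered grid (guaranteed
  ## minimum separation, random placement within each slot)
  margin <- min(5000L, floor(config$genomeLength / 10))
  minSep <- 200L
  pos <- integer(0)
  if (nTotal) {
    usable <- config$genomeLength - 2L * margin
    slot <- usable %/% nTotal
    if (slot <= minSep)
      stop("insertion-space exhaustion: placed 0 of ", nTotal,
           " copies (genome too small for the requested copy numbers)")
    jitter <- sample.int(slot - minSep, nTotal, replace = TRUE) - 1L
    pos <- margin + (seq_len(nTotal) - 1L) * slot + jitter
    ord <- sample.int(nTotal)   # random copy-to-position assignment
    plan <- plan[ord, , drop = FALSE]
    srcSeq <- srcSeq[ord]; evSeq <- evSeq[ord]; insSeq <- insSeq[ord]
    insLen <- insLen[ord]; realized <- realized[ord]
  }

  ## assemble genome and ground-truth coordinates
  if (nTotal) {
    k <- plan$tsd_length
    segStart <- c(1L, pos)
    segEnd <- c(pos + k - 1L, config$genomeLength)
    segs <- substring(bg, segStart, segEnd)
    pieces <- character(2 * nTotal + 1)
    pieces[seq(1, 2 * nTotal + 1, by = 2)] <- segs
    pieces[seq(2, 2 * nTotal, by = 2)] <- insSeq
    genomeSeq <- paste(pieces, collapse = "")
    offs <- cumsum(c(0, insLen[-nTotal] + k[-nTotal]))
    starts <- pos + k + offs
    ends <- starts + insLen - 1L
    tsdSeq <- ifelse(k > 0, substring(bg, pos, pos + k - 1L), "")
  } else {
    genomeSeq <- bg
    starts <- ends <- integer(0); tsdSeq <- character(0)
  }

  genome <- DNAStringSet(setNames(genomeSeq, "chr1"))
  copies <- GRanges(rep("chr1", nTotal), IRanges(start = starts, end = ends),
                    strand = if (nTotal) plan$strand else character(0))
  if (nTotal) {
    mcols(copies) <- DataFrame(
      family = plan$family, subfamily = plan$family, class = plan$class,
      structure = plan$structure, tsd = tsdSeq, tsd_length = plan$tsd_length,
      truncation = plan$trunc, nominal_divergence = plan$nominal,
      realized_divergence = realized,
      copy_id = sprintf("%s_%04d", plan$family, plan$idx))
  }
  new("TESimulation", genome = genome, truth = truth, copies = copies,
      config = unclass(config))
}

## resample background windows sharing an exact 30-mer with a truth consensus
scrubBackground <- function(bg, tseq, gc, k = 30L, maxIter = 10L) {
  if (!length(tseq)) return(bg)
  pats <- unlist(lapply(tseq, function(s) {
    if (nchar(s) < k) return(character(0))
    st <- seq_len(nchar(s) - k + 1L)
    substring(s, st, st + k - 1L)
  }), use.names = FALSE)
  pats <- unique(c(pats, revcompChr(pats)))
  pd <- PDict(DNAStringSet(pats))
  for (iter in seq_len(maxIter)) {
    m <- matchPDict(pd, DNAString(bg))
    hits <- unlist(IRanges::IRangesList(lapply(m, IRanges::ranges)))
    if (!length(hits)) return(bg)
    hits <- IRanges::reduce(hits)
    x <- chars(bg)
    for (j in seq_along(hits)) {
      s <- IRanges::start(hits)[j]; e <- IRanges::end(hits)[j]
      x[s:e] <- chars(randomSeq(e - s + 1L, gc))
    }
    bg <- paste(x, collapse = "")
  }
  bg
}

#' Simulate several genomes sharing one truth library, along a species tree
#'
#' Each family is "gained" on one branch of a rooted species tree and is then
#' inserted (independently evolved from the shared truth consensus) into every
#' genome descending from that branch. Background sequences are independent
#' per genome.
#'
#' @param config a [simConfig()] whose families cover all genomes.
#' @param tree an `ape::phylo` rooted tree (or Newick string/file path).
#' @param gains named character vector: family name -> branch label as
#'   produced by [branchLabels()].
#' @return list with elements `sims` (named list of [TESimulation-class], one
#'   per tip), `truth`, `gains`, `tree`.
#' @export
simulateClade <- function(config, tree, gains) {
  tree <- asPhylo(tree)
  stopifnot(all(names(config$families) %in% names(gains)) ||
              all(names(gains) %in% names(config$families)))
  labs <- branchLabels(tree)
  if (!all(gains %in% labs))
    stop("unknown branch label(s): ", paste(setdiff(gains, labs), collapse = ", "))
  truth <- makeTruthLibrary(config)
  sims <- list()
  for (i in seq_along(tree$tip.label)) {
    tip <- tree$tip.label[i]
    present <- names(gains)[vapply(gains, function(b)
      tip %in% branchTips(tree, b), logical(1))]
    cfg <- config
    cfg$families <- config$families[intersect(names(config$families), present)]
    cfg$seed <- deriveSeed(config$seed, i)
    sims[[tip]] <- simulateGenome(cfg, truth = truth[names(cfg$families)])
    names(sims[[tip]]@genome) <- tip
    cp <- GenomicRanges::GRanges(tip, IRanges::ranges(sims[[tip]]@copies),
                                 strand = GenomicRanges::strand(sims[[tip]]@copies))
    mcols(cp) <- mcols(sims[[tip]]@copies)
    sims[[tip]]@copies <- cp
  }
  list(sims = sims, truth = truth, gains = gains, tree = tree)
}

#' Derive a degraded "predicted" seed library from a truth library
#'
#' Emulates the de-novo prediction step whose output is the curation input:
#' every truth consensus is mutated at `divergence`, and CR1 seeds are
#' clipped to their 3'-terminal `cr1SeedLength` bp (de-novo CR1 predictions
#' are dominated by the 3'-anchored portion shared by most copies). Seeds are
#' emitted unclassified, as prediction would leave them.
#'
#' @param truth a [ConsensusLibrary-class] from [makeTruthLibrary()].
#' @param config the matching [simConfig()].
#' @param divergence per-site mutation rate applied to each seed.
#' @param cr1SeedLength 3' length retained for CR1 seeds.
#' @param seed RNG seed for the degradation step.
#' @return a [ConsensusLibrary-class] of unclassified seeds with a
#'   `true_family` annotation column.
#' @export
makeSeedLibrary <- function(truth, config, divergence = 0.03,
                            cr1SeedLength = 1200, seed = config$seed + 1) {
  set.seed(seed)
  tseq <- as.character(consensusSeqs(truth))
  info <- consensusInfo(truth)
  out <- character(length(tseq))
  for (i in seq_along(tseq)) {
    s <- evolveCopy(tseq[[i]], divergence, config)
    if (info$class[i] == "LINE/CR1" && nchar(s) > cr1SeedLength)
      s <- substr(s, nchar(s) - cr1SeedLength + 1, nchar(s))
    out[i] <- s
  }
  names(out) <- sprintf("pred_%02d", seq_along(out))
  lib <- ConsensusLibrary(DNAStringSet(out))
  lib@info$class <- "Unknown"
  lib@info$true_family <- info$name
  lib@info$source <- "simulated prediction"
  lib
}
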