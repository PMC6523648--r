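# Shared small simulation fixture, built once per test run.
.fx <- new.env(parent = emptyenv())

# ~500 kb genome with two ERV families and one CR1 family; used by the
# curation and landscape tests.
smallSim <- function() {
  if (is.null(.fx$small)) {
    cfg <- simConfig(genomeLength = 5e5, gcContent = 0.42, seed = 11,
                     families = list(
      familySpec("ERV_A", "ERV", ltrLength = 300, internalLength = 2000,
                 tsdLength = 6, copyNumber = 25, divergence = 0.05,
                 soloLtrProb = 0.4),
      familySpec("ERV_B", "ERV", ltrLength = 250, internalLength = 1500,
                 tsdLength = 4, copyNumber = 20, divergence = 0.03,
                 soloLtrProb = 0.6),
      familySpec("CR1_A", "CR1", totalLength = 3500, copyNumber = 30,
                 divergence = 0.06, cr1TruncationMean = 800)))
    sim <- simulateGenome(cfg)
    class(cfg) <- "simConfig"
    .fx$small <- list(cfg = cfg, sim = sim,
                      seeds = makeSeedLibrary(simTruth(sim), cfg))
  }
  .fx$small
}

# curated library for the small fixture (computed once)
smallCuration <- function() {
  if (is.null(.fx$smallCur)) {
    fx <- smallSim()
    .fx$smallCur <- curateLibrary(fx$seeds, simGenome(fx$sim))
  }
  .fx$smallCur
}

# identity/coverage of a curated consensus against its truth consensus
recoveryOf <- function(curatedSeq, truthSeq) {
  h <- seedExtendSearch(as.character(curatedSeq),
                        Biostrings::DNAStringSet(c(t = as.character(truthSeq))),
                        minScore = 50)
  if (!length(h)) return(list(coverage = 0, identity = 0))
  m <- S4Vectors::mcols(h)
  w <- m$qend - m$qstart + 1
  list(coverage = sum(IRanges::width(IRanges::reduce(IRanges::ranges(h)))) /
         nchar(as.character(truthSeq)),
       identity = sum(m$pid * w) / sum(w))
}
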