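test_that("truth library enforces ERV and CR1 structural motifs", {
  cfg <- simConfig(genomeLength = 1e5, seed = 3, families = list(
    familySpec("E", "ERV", ltrLength = 300, internalLength = 2000,
               tsdLength = 6, copyNumber = 0),
    familySpec("C", "CR1", totalLength = 4000, copyNumber = 0),
    familySpec("S", "SINE", totalLength = 150, copyNumber = 0)))
  lib <- makeTruthLibrary(cfg)
  e <- as.character(consensusSeqs(lib)[["E"]])
  expect_equal(nchar(e), 2600)
  expect_equal(substr(e, 1, 2), "TG")
  expect_equal(substr(e, 299, 300), "CA")
  expect_equal(substr(e, 2301, 2302), "TG")
  expect_equal(substr(e, 2599, 2600), "CA")
  # both LTRs identical
  expect_equal(substr(e, 1, 300), substr(e, 2301, 2600))
  cc <- as.character(consensusSeqs(lib)[["C"]])
  expect_match(substr(cc, 3993, 4000), "^ATTCT[AG]TG$")
  # determinism: byte-identical on re-run
  lib2 <- makeTruthLibrary(cfg)
  expect_identical(as.character(consensusSeqs(lib2)),
                   as.character(consensusSeqs(lib)))
  # invalid geometries are rejected
  expect_error(familySpec("bad", "ERV", ltrLength = 6, internalLength = 100),
               "ltrLength")
  expect_error(familySpec("bad", "CR1", totalLength = 6), "totalLength")
})

test_that("evolveCopy honours the zero-rate and rate-one limits", {
  cfg <- simConfig(seed = 1, families = list())
  s <- rseq(2000, gc = 0.45)
  expect_identical(evolveCopy(s, 0, cfg), s)
  cfgA <- simConfig(seed = 1, families = list(), apobecRate = 1)
  ed <- evolveCopy(s, 0, cfgA)
  expect_false(grepl("G", ed))
  x <- strsplit(s, "")[[1]]; y <- strsplit(ed, "")[[1]]
  expect_true(all(y[x != "G"] == x[x != "G"]))  # only Gs were edited
})

test_that("realized divergence matches the per-site expectation oracle", {
  cfg <- simConfig(seed = 9, families = list(), kappa = 2, cpgMultiplier = 10)
  set.seed(9)
  cons <- rseq(10000, gc = 0.45)
  d <- 0.05
  nrep <- 60
  fr <- replicate(nrep, {
    ev <- evolveCopy(cons, d, cfg)
    mean(strsplit(ev, "")[[1]] != strsplit(cons, "")[[1]])
  })
  expected <- expectedSubstFraction(cons, d)
  se <- sd(fr) / sqrt(nrep)
  expect_lt(abs(mean(fr) - expected), 3 * se + 1e-6)
  # CpG acceleration shows up where it should
  expect_gt(expected, d)   # CpG sites raise the genome-wide expectation
})

test_that("insertions carry exact TSDs, exact solo counts and geometric CR1 truncation", {
  cfg <- simConfig(genomeLength = 2e6, seed = 31, families = list(
    familySpec("E4", "ERV", ltrLength = 250, internalLength = 1200,
               tsdLength = 4, copyNumber = 30, divergence = 0.05,
               soloLtrProb = 0.5),
    familySpec("CT", "CR1", totalLength = 3000, copyNumber = 200,
               divergence = 0.03, cr1TruncationMean = 1500)))
  sim <- simulateGenome(cfg)
  g <- simGenome(sim)[["chr1"]]
  cp <- simCopies(sim)
  m <- S4Vectors::mcols(cp)

  ## TSD conservation for every ERV copy
  erv <- which(m$family == "E4")
  for (i in erv) {
    k <- m$tsd_length[i]
    s <- IRanges::start(cp)[i]; e <- IRanges::end(cp)[i]
    left <- as.character(XVector::subseq(g, s - k, s - 1))
    right <- as.character(XVector::subseq(g, e + 1, e + k))
    expect_identical(left, right)
    expect_identical(left, m$tsd[i])
    expect_equal(k, 4L)
  }
  ## exact solo fraction
  expect_equal(sum(m$structure[erv] == "solo_LTR"), 15)
  ## solo copies are one LTR long
  solo <- erv[m$structure[erv] == "solo_LTR"]
  expect_true(all(IRanges::width(cp)[solo] == 250))
  ## CR1 truncation: mean within 3 SE of the censored-geometric closed form
  ## (draws are capped at totalLength - 200 so a 3' anchor always remains):
  ## E[min(X, c)] = (1-p) (1 - (1-p)^c) / p for X ~ Geom(p) on 0,1,2,...
  tr <- m$truncation[m$family == "CT"]
  p <- 1 / (1 + 1500); cap <- 3000 - 200
  muCens <- (1 - p) * (1 - (1 - p)^cap) / p
  expect_lt(abs(mean(tr) - muCens), 3 * sd(tr) / sqrt(length(tr)))
  ## copies never overlap
  expect_equal(sum(IRanges::width(IRanges::reduce(IRanges::ranges(cp)))),
               sum(IRanges::width(cp)))
})

test_that("same config and seed reproduce the genome byte for byte", {
  cfg <- simConfig(genomeLength = 2e5, seed = 12, families = list(
    familySpec("E", "ERV", ltrLength = 200, internalLength = 800,
               tsdLength = 5, copyNumber = 10, divergence = 0.04,
               soloLtrProb = 0.2)))
  s1 <- simulateGenome(cfg)
  s2 <- simulateGenome(cfg)
  expect_identical(as.character(simGenome(s1)), as.character(simGenome(s2)))
  expect_identical(as.data.frame(simCopies(s1)), as.data.frame(simCopies(s2)))
  ## different seed, different genome
  cfg$seed <- 13L
  s3 <- simulateGenome(cfg)
  expect_false(identical(as.character(simGenome(s1)),
                         as.character(simGenome(s3))))
})

test_that("background contains no exact 30-mer from any truth consensus", {
  cfg <- simConfig(genomeLength = 3e5, seed = 8, families = list(
    familySpec("E", "ERV", ltrLength = 220, internalLength = 1000,
               tsdLength = 6, copyNumber = 0)))
  sim <- simulateGenome(cfg)
  cons <- as.character(consensusSeqs(simTruth(sim))[[1]])
  st <- seq_len(nchar(cons) - 29)
  kmers <- unique(substring(cons, st, st + 29))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  n <- sum(S4Vectors::elementNROWS(
    Biostrings::matchPDict(pd, simGenome(sim)[["chr1"]])))
  expect_equal(n, 0)
})

test_that("solo probability one yields only solo-LTR structures", {
  cfg <- simConfig(genomeLength = 1e6, seed = 4, families = list(
    familySpec("E", "ERV", ltrLength = 300, internalLength = 2000,
               tsdLength = 6, copyNumber = 50, divergence = 0.02,
               soloLtrProb = 1)))
  sim <- simulateGenome(cfg)
  st <- S4Vectors::mcols(simCopies(sim))$structure
  expect_equal(sum(st == "solo_LTR"), 50)
  expect_equal(sum(st == "full_length"), 0)
})
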