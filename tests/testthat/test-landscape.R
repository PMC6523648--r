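test_that("K2P with unit CpG weight equals the closed form to 1e-12", {
  ## identical rows
  expect_equal(as.numeric(kimura2p(strrep("ACGT", 50), strrep("ACGT", 50))), 0)
  ## random alignments, transition/transversion counting done independently
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(50:400, 1)
    a <- strsplit(rseq(n), "")[[1]]
    b <- a
    nm <- sample(0:floor(n / 4), 1)
    idx <- sample(n, nm)
    for (j in idx) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
    nts <- sum(paste0(a[idx], b[idx]) %in% c("AG", "GA", "CT", "TC"))
    P <- nts / n
    Q <- (nm - nts) / n
    ref <- bruteK2P(P, Q)
    if (!is.finite(ref) || (1 - 2 * P - Q) <= 0) next
    got <- kimura2p(paste(a, collapse = ""), paste(b, collapse = ""),
                    cpgWeight = 1)
    expect_equal(as.numeric(got), ref, tolerance = 1e-12)
  }
})

test_that("the worked K2P case and CpG down-weighting behave as derived", {
  ## 1000 countable columns, 100 transitions, 50 transversions, no CpG:
  ## K = -0.5 ln(0.75 sqrt(0.90)) = 0.1702 (4 d.p.)
  cons <- strrep("AT", 500)               # CpG-free consensus
  x <- strsplit(cons, "")[[1]]
  x[seq(1, 199, by = 2)] <- "G"           # 100 A->G transitions
  x[seq(300, 398, by = 2)] <- "G"         # 50 T->G transversions
  copy <- paste(x, collapse = "")
  expect_equal(round(as.numeric(kimura2p(cons, copy, cpgWeight = 1)), 4), 0.1702)
  expect_equal(as.numeric(kimura2p(cons, copy, cpgWeight = 1)),
               bruteK2P(0.1, 0.05), tolerance = 1e-12)
  ## all transitions at consensus CpG sites, weight 0.1: P drops 10x, K smaller
  consC <- strrep("CGTTA", 200)           # CpG at positions 1-2 of each repeat
  y <- strsplit(consC, "")[[1]]
  y[seq(1, 496, by = 5)] <- "T"           # C->T transitions at 100 CpG sites
  copyC <- paste(y, collapse = "")
  kW <- as.numeric(kimura2p(consC, copyC, cpgWeight = 0.1))
  k1 <- as.numeric(kimura2p(consC, copyC, cpgWeight = 1))
  expect_lt(kW, k1)
  ## gaps and Ns are excluded from counting
  expect_equal(as.numeric(kimura2p("AC-GT", "ACN-T", cpgWeight = 1)), 0)
  expect_error(kimura2p("---", "AAA"), "countable")
  ## saturation returns the capped sentinel
  sat <- kimura2p(strrep("A", 100), strrep("G", 100), cpgWeight = 1)
  expect_equal(as.numeric(sat), 0.5)
  expect_true(attr(sat, "saturated"))
})

test_that("K2P is non-decreasing in P and Q on its domain", {
  for (P in seq(0, 0.3, by = 0.05)) for (Q in seq(0, 0.2, by = 0.05)) {
    if (1 - 2 * (P + 0.01) - (Q + 0.01) <= 0) next
    expect_gte(bruteK2P(P + 0.01, Q), bruteK2P(P, Q))
    expect_gte(bruteK2P(P, Q + 0.01), bruteK2P(P, Q))
  }
})

test_that("landscape bins conserve masked bp and recover two bursts", {
  cfg <- simConfig(genomeLength = 8e5, seed = 27, families = list(
    familySpec("B", "ERV", ltrLength = 250, internalLength = 1500,
               tsdLength = 6, copyNumber = 40,
               divergence = c(0.02, 0.15), soloLtrProb = 0)))
  sim <- simulateGenome(cfg)
  track <- maskGenome(simTruth(sim), simGenome(sim))
  lt <- landscapeTable(track)
  ## bp conservation
  expect_equal(sum(lt$bp), sum(IRanges::width(maskHits(track))))
  ## bimodality: two local maxima near the expectations of the landscape
  ## statistic (CpG-down-weighted K2P).  Oracle: simulate copies under the
  ## same per-site model and evaluate the weighted estimator independently.
  class(cfg) <- "simConfig"
  cons <- as.character(consensusSeqs(simTruth(sim))[[1]])
  oracleBin <- function(d) {
    ks <- replicate(30, bruteWeightedK2P(cons, evolveCopy(cons, d, cfg)))
    floor(mean(ks) * 100)
  }
  modes <- landscapeModes(lt)
  set.seed(101)
  expected <- sort(c(oracleBin(0.02), oracleBin(0.15)))
  expect_lte(abs(modes[1] - expected[1]), 1)
  expect_lte(abs(modes[2] - expected[2]), 1)
  ## empty track gives an all-zero table
  empty <- new("MaskTrack", hits = tecur:::emptyHits(), genomeLength = 1e5,
               seqLengths = c(chr1 = 100000L),
               library = S4Vectors::DataFrame(name = character(0),
                                              class = character(0)))
  lt0 <- landscapeTable(empty)
  expect_true(all(lt0$bp == 0))
})

test_that("the summary table follows the annotation-summary layout", {
  fx <- smallSim()
  track <- maskGenome(simTruth(fx$sim), simGenome(fx$sim))
  st <- summaryTable(track)
  expect_equal(st$type, c("SINE", "LINE", "LTR", "DNA", "Unclassified",
                          "Total interspersed repeats"))
  ## class totals sum to the total row
  expect_equal(sum(st$bp[1:5]), st$bp[6])
  expect_equal(sum(st$copies[1:5]), st$copies[6])
  expect_equal(st$pct, round(100 * st$bp / genomeLength(track), 2))
  ## masked bp per class within 5% of ground truth (all copies <= 20% diverged)
  cp <- simCopies(fx$sim)
  m <- S4Vectors::mcols(cp)
  truthLTR <- sum(IRanges::width(cp)[m$class == "ERV"])
  expect_lt(abs(st$bp[st$type == "LTR"] - truthLTR) / truthLTR, 0.05)
  truthLINE <- sum(IRanges::width(cp)[m$class == "CR1"])
  expect_lt(abs(st$bp[st$type == "LINE"] - truthLINE) / truthLINE, 0.05)
})

test_that("overlap ratios follow intersect semantics and monotonicity", {
  fx <- smallSim()
  track <- maskGenome(simTruth(fx$sim), simGenome(fx$sim))
  h <- maskHits(track)
  expect_equal(overlapRatio(track, h)$ratio, 1.0)
  far <- GenomicRanges::shift(h[1:10], 100000)
  ## shifted into unmasked background: no overlaps
  disjoint <- far[!IRanges::overlapsAny(far, h, ignore.strand = TRUE)]
  if (length(disjoint))
    expect_equal(overlapRatio(track, disjoint)$ratio, 0.0)
  expect_error(overlapRatio(track, h[0]), "empty")
  ## growing the baseline can only increase the ratio
  half <- h[seq(1, length(h), by = 2)]
  r1 <- overlapRatio(half, h)$ratio
  r2 <- overlapRatio(h, h)$ratio
  expect_lte(r1, r2)
})
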