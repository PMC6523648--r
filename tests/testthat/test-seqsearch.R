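test_that("self-match, strand symmetry and the mismatch score arithmetic", {
  set.seed(42)
  bg <- rseq(20000)
  q <- substr(bg, 5001, 5500)
  g <- Biostrings::DNAStringSet(c(chr = bg))
  h <- seedExtendSearch(q, g)
  expect_gte(length(h), 1)
  m <- S4Vectors::mcols(h)
  expect_equal(m$pid[1], 1.0)
  expect_equal(m$qstart[1], 1); expect_equal(m$qend[1], 500)
  expect_equal(IRanges::start(h)[1], 5001)
  expect_equal(m$score[1], 1000)

  ## reverse complement of the query: one hit, minus strand, same score
  qr <- chartr("ACGT", "TGCA", paste(rev(strsplit(q, "")[[1]]), collapse = ""))
  h2 <- seedExtendSearch(qr, g)
  expect_equal(as.character(GenomicRanges::strand(h2))[1], "-")
  expect_equal(S4Vectors::mcols(h2)$score[1], 1000)

  ## query with exactly 10 scattered mismatches in 500 bp
  set.seed(7)
  qm <- mutateExact(q, 10)
  h3 <- seedExtendSearch(qm, g)
  m3 <- S4Vectors::mcols(h3)
  expect_equal(m3$score[1], 500 * 2 - 10 * (2 + 3))
  expect_equal(m3$pid[1], 0.98)
})

test_that("search errors and degenerate inputs behave per contract", {
  expect_error(seedExtendSearch("ACGTACGT", Biostrings::DNAStringSet(c(a = "ACGT"))),
               "shorter than seed")
  qn <- paste(c(rep("N", 60), rep("A", 40)), collapse = "")
  expect_error(seedExtendSearch(qn, Biostrings::DNAStringSet(c(a = rseq(100)))),
               "50% N")
  h <- seedExtendSearch(rseq(100), Biostrings::DNAStringSet())
  expect_equal(length(h), 0)
})

test_that("top-hit score equals brute-force Smith-Waterman on small instances", {
  set.seed(11)
  for (rep in 1:6) {
    bg <- rseq(1500)
    core <- rseq(220)
    insert <- if (rep %% 2 == 0) {
      ## plant an indel: 6 bp deleted from the middle of the copy
      paste0(substr(core, 1, 100), substr(core, 107, 220))
    } else mutateExact(core, 12)
    g <- paste0(substr(bg, 1, 700), insert, substr(bg, 701, 1500))
    h <- seedExtendSearch(core, Biostrings::DNAStringSet(c(chr = g)),
                          minScore = 30)
    expect_gte(length(h), 1)
    sw <- bruteSW(core, g)
    expect_equal(max(S4Vectors::mcols(h)$score), sw)
  }
})

test_that("overlap resolution is greedy by score with boundary trimming", {
  mkhit <- function(start, len, score, q = "q") {
    gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(start, start + len - 1),
                                 strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      query = q, qstart = 1L, qend = len, score = score, pid = 0.95,
      evalue = 1e-20, aln_q = strrep("A", len), aln_t = strrep("A", len))
    gr
  }
  ## identical intervals: only the better hit survives
  r <- resolveOverlaps(c(mkhit(100, 400, 900, "a"), mkhit(100, 400, 700, "b")))
  expect_equal(length(r), 1)
  expect_equal(S4Vectors::mcols(r)$query, "a")
  ## partial 100-bp overlap: lower 400-bp hit trimmed to 300 bp
  r2 <- resolveOverlaps(c(mkhit(100, 400, 900, "a"), mkhit(400, 400, 700, "b")))
  r2b <- r2[S4Vectors::mcols(r2)$query == "b"]
  expect_equal(IRanges::width(r2b), 300)
  expect_equal(IRanges::start(r2b), 500)
  ## fragments shorter than 20 bp are dropped
  r3 <- resolveOverlaps(c(mkhit(100, 400, 900, "a"), mkhit(485, 30, 50, "b")))
  expect_equal(S4Vectors::mcols(r3)$query, "a")
})

test_that("resolution matches exhaustive greedy admissibility on random sets", {
  ## oracle: apply the greedy rule by hand over all hits in score order
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    starts <- sample(1:500, n)
    lens <- sample(30:150, n, replace = TRUE)
    scores <- sample(seq(100, 900, by = 17), n)
    hits <- do.call(c, lapply(seq_len(n), function(i) {
      gr <- GenomicRanges::GRanges("chr",
                                   IRanges::IRanges(starts[i], starts[i] + lens[i] - 1),
                                   strand = "+")
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        query = paste0("q", i), qstart = 1L, qend = lens[i],
        score = scores[i], pid = 0.9, evalue = 1e-10,
        aln_q = strrep("A", lens[i]), aln_t = strrep("A", lens[i]))
      gr
    }))
    res <- resolveOverlaps(hits)
    ## oracle bp set: greedy coverage in score order
    ord <- order(-scores, starts)
    covered <- integer(0)
    kept <- integer(0)
    for (i in ord) {
      iv <- setdiff(starts[i]:(starts[i] + lens[i] - 1), covered)
      runs <- split(iv, cumsum(c(1, diff(iv) != 1)))
      iv <- unlist(runs[vapply(runs, length, integer(1)) >= 20])
      if (length(iv)) { covered <- c(covered, iv); kept <- c(kept, i) }
    }
    got <- sort(unlist(lapply(seq_along(res), function(j)
      IRanges::start(res)[j]:IRanges::end(res)[j])))
    expect_equal(unname(got), unname(sort(covered)))
  }
})

test_that("masking covers ground truth and totals stay within genome length", {
  cfg <- simConfig(genomeLength = 5e5, seed = 19, families = list(
    familySpec("E1", "ERV", ltrLength = 250, internalLength = 1500,
               tsdLength = 4, copyNumber = 15, divergence = 0.05,
               soloLtrProb = 0.3),
    familySpec("C1", "CR1", totalLength = 2500, copyNumber = 15,
               divergence = 0.08, cr1TruncationMean = 600)))
  sim <- simulateGenome(cfg)
  g <- simGenome(sim)
  track <- maskGenome(simTruth(sim), g)
  hits <- maskHits(track)
  ## >= 95% of ground-truth TE bp recovered (all copies are <= 20% diverged)
  cp <- simCopies(sim)
  ov <- IRanges::intersect(IRanges::reduce(IRanges::ranges(hits)),
                           IRanges::reduce(IRanges::ranges(cp)))
  expect_gte(sum(IRanges::width(ov)) / sum(IRanges::width(cp)), 0.95)
  ## masked totals bounded by genome length
  ct <- classTotals(track)
  expect_lte(sum(ct$bp), genomeLength(track))
  ## monotone, additive behaviour for a sub-library
  sub <- maskGenome(simTruth(sim)["E1"], g)
  expect_lte(sum(classTotals(sub)$bp), sum(ct$bp))
  ## ambiguous labels are rejected as early as library construction
  expect_error(c(simTruth(sim), simTruth(sim)), "unique")
})

test_that("same region matched by two consensuses keeps the better label", {
  set.seed(2)
  fam <- rseq(800)
  sub1 <- mutateExact(fam, 16)   # 2% off
  sub2 <- mutateExact(fam, 120)  # 15% off
  g <- Biostrings::DNAStringSet(c(chr = paste0(rseq(2000), fam, rseq(2000))))
  lib <- ConsensusLibrary(Biostrings::DNAStringSet(c(near = sub1, far = sub2)))
  track <- maskGenome(lib, g, minScore = 100)
  h <- maskHits(track)
  ## the near-identical consensus wins the locus
  best <- S4Vectors::mcols(h)$query[which.max(S4Vectors::mcols(h)$score)]
  expect_equal(best, "near")
  bigger <- h[IRanges::width(h) > 100]
  expect_true(all(S4Vectors::mcols(bigger)$query == "near"))
})
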