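test_that("selection for curation keeps only >5%-diverged predictions", {
  set.seed(21)
  known <- rseq(1000)
  identical_ <- known
  diverged <- mutateExact(known, 70)          # ~7% diverged
  ## exactly 5% diverged: 50 evenly spread mismatches, none at the ends
  x <- strsplit(known, "")[[1]]
  for (i in seq(10, 990, by = 20)) x[i] <- setdiff(c("A","C","G","T"), x[i])[1]
  boundary <- paste(x, collapse = "")
  novel <- rseq(900)
  pred <- ConsensusLibrary(Biostrings::DNAStringSet(
    c(p_ident = identical_, p_div = diverged, p_bound = boundary,
      p_novel = novel)))
  ref <- ConsensusLibrary(Biostrings::DNAStringSet(c(known = known)))
  keep <- names(selectForCuration(pred, ref))
  expect_false("p_ident" %in% keep)
  expect_true("p_div" %in% keep)
  expect_false("p_bound" %in% keep)   # the rule is strictly more than 5%
  expect_true("p_novel" %in% keep)
})

test_that("hit collection returns the n best deduplicated, oriented rows", {
  fx <- smallSim()
  g <- simGenome(fx$sim)
  cons <- as.character(consensusSeqs(simTruth(fx$sim))[["ERV_A"]])
  fl <- collectHits(cons, g, n = 20)
  expect_length(fl, 20)
  ## rows are pairwise non-overlapping loci
  hits <- do.call(c, lapply(fl, `[[`, "hit"))
  expect_equal(sum(IRanges::width(IRanges::reduce(IRanges::ranges(hits)))),
               sum(IRanges::width(hits)))
  ## a single-copy family is uncuratable
  g1 <- Biostrings::DNAStringSet(c(chr = paste0(rseq(3000), cons, rseq(3000))))
  expect_error(collectHits(cons, g1), class = "tecur_uncuratable")
})

test_that("majority consensus follows abundance, ties, gaps and the CpG rule", {
  mkAln <- function(rows) {
    mat <- do.call(rbind, strsplit(rows, ""))
    new("CurationAlignment", mat = mat,
        isCore = matrix(TRUE, nrow(mat), ncol(mat)), offset = 0L,
        consensusName = "t", hits = GenomicRanges::GRanges())
  }
  ## plurality wins: column of 12 A + 8 G
  aln <- mkAln(c(rep("AT", 12), rep("GT", 8)))
  expect_equal(buildConsensus(aln, 1:2, cpgRule = FALSE)$sequence, "AT")
  ## fixed tie order A < C < G < T
  aln2 <- mkAln(c("CA", "CA", "TA", "TA"))
  expect_equal(substr(buildConsensus(aln2, 1:2, cpgRule = FALSE)$sequence, 1, 1), "C")
  ## gap wins only above half, and drops the column
  aln3 <- mkAln(c("A-G", "A-G", "A-G", "ACG", "ACG"))
  expect_equal(buildConsensus(aln3, 1:3, cpgRule = FALSE)$sequence, "AG")
  ## CpG rule: 40% CG / 60% TG -> CG
  aln4 <- mkAln(c(rep("CG", 4), rep("TG", 6)))
  out4 <- buildConsensus(aln4, 1:2, cpgRule = TRUE)
  expect_equal(out4$sequence, "CG")
  expect_equal(out4$cpgRestored, c(1L, 2L))
  ## ...and with the rule off the plurality stands
  expect_equal(buildConsensus(aln4, 1:2, cpgRule = FALSE)$sequence, "TG")
  ## CA -> CG on the second position
  aln5 <- mkAln(c(rep("CG", 4), rep("CA", 6)))
  expect_equal(buildConsensus(aln5, 1:2, cpgRule = TRUE)$sequence, "CG")
  ## sporadic CG (below a quarter of rows) does not trigger the rule
  aln6 <- mkAln(c(rep("CG", 2), rep("TG", 14)))
  expect_equal(buildConsensus(aln6, 1:2, cpgRule = TRUE)$sequence, "TG")
})

test_that("the CpG rule never touches columns outside TG/CA dinucleotides", {
  fx <- smallSim()
  g <- simGenome(fx$sim)
  cons <- as.character(consensusSeqs(simTruth(fx$sim))[["ERV_B"]])
  fl <- collectHits(cons, g, n = 15)
  aln <- buildCurationAlignment(fl, nchar(cons), 2000, "ERV_B")
  bd <- detectBoundaries(aln)
  on <- buildConsensus(bd$aln, bd$start:bd$end, cpgRule = TRUE)
  off <- buildConsensus(bd$aln, bd$start:bd$end, cpgRule = FALSE)
  a <- strsplit(on$sequence, "")[[1]]
  b <- strsplit(off$sequence, "")[[1]]
  d <- which(a != b)
  ## every difference is T->C or A->G (the rule only restores CpG)
  expect_true(all((b[d] == "T" & a[d] == "C") | (b[d] == "A" & a[d] == "G")))
})

test_that("boundary detection recovers the element core to within 10 bp", {
  fx <- smallSim()
  g <- simGenome(fx$sim)
  truthLen <- c(ERV_A = 2600L, ERV_B = 2000L)
  for (fam in names(truthLen)) {
    cons <- as.character(consensusSeqs(simTruth(fx$sim))[[fam]])
    fl <- collectHits(cons, g, n = 20)
    aln <- buildCurationAlignment(fl, nchar(cons), 2000, fam)
    bd <- detectBoundaries(aln)
    expect_lt(abs((bd$end - bd$start + 1L) - truthLen[[fam]]), 10)
  }
})

test_that("copies sharing identical flanks are flagged ambiguous-boundary", {
  set.seed(31)
  elem <- rseq(900)
  f1 <- rseq(700); f2 <- rseq(700)
  g <- Biostrings::DNAStringSet(c(chr = paste0(
    rseq(2500), f1, mutateExact(elem, 18), f2,
    rseq(2500), f1, mutateExact(elem, 18), f2,
    rseq(2500), f1, mutateExact(elem, 18), f2, rseq(2500))))
  fl <- collectHits(elem, g, n = 5)
  aln <- buildCurationAlignment(fl, nchar(elem), 2000, "deg")
  bd <- detectBoundaries(aln)
  expect_true("ambiguous-boundary" %in% bd$flags)
  ## the boundary extended into the shared flank
  expect_gt((bd$end - bd$start + 1L), nchar(elem) + 500)
})

test_that("TSD detection matches ground truth and aggregates per superfamily", {
  fx <- smallSim()
  g <- simGenome(fx$sim)
  cp <- simCopies(fx$sim)
  m <- S4Vectors::mcols(cp)
  idx <- which(m$family == "ERV_A" & m$structure == "full_length")[1:5]
  for (i in idx) {
    td <- detectTSD(g, "chr1", IRanges::start(cp)[i], IRanges::end(cp)[i])
    expect_equal(td$best$k, 6)
    expect_equal(td$best$seq, m$tsd[i])
  }
  ## homopolymer-like TSDs legitimately match at several k
  gg <- Biostrings::DNAStringSet(c(chr1 = paste0(
    rseq(300), "AAAAAA", rseq(500), "AAAAAA", rseq(300))))
  td <- detectTSD(gg, "chr1", 307, 806)
  expect_true(all(c(4, 5, 6) %in% td$matches$k))
  expect_equal(td$best$k, 6)   # maximal k at the best offset
})

test_that("chance TSD matches occur at the analytic background rate", {
  set.seed(77)
  n <- 600
  gc <- 0.5
  g <- Biostrings::DNAStringSet(c(chr = rseq(200 * n + 400, gc = gc)))
  hits <- 0
  for (i in seq_len(n)) {
    s <- 200 * i; e <- s + 120
    td <- detectTSD(g, "chr1", s, e, jitter = 0)
    if (!is.null(td$best)) hits <- hits + 1
  }
  q <- vapply(4:6, function(k) 0.25^k, numeric(1))  # uniform composition
  pAnalytic <- 1 - prod(1 - q)
  se <- sqrt(pAnalytic * (1 - pAnalytic) / n)
  expect_lt(abs(hits / n - pAnalytic), 3 * se + 2 / n)
})

test_that("LTR end report and CR1 octamer location follow their contracts", {
  expect_true(checkLtrEnds("TGAAACCCCA")$canonical)
  v <- checkLtrEnds("TGAAACCCTA")
  expect_false(v$canonical)
  expect_equal(v$variant, "TG...TA")
  expect_error(checkLtrEnds("TGA"), "short")
  s <- paste0(rseq(3992), "ATTCTATG")
  expect_equal(findCr1ThreePrime(s), 3993L)
  s2 <- paste0(rseq(3992), "ATTCTGTG")
  expect_equal(findCr1ThreePrime(s2), 3993L)
  ## motif far from the 3' end is not accepted
  s3 <- paste0(rseq(9), "ATTCTATG", rseq(4000))
  expect_null(findCr1ThreePrime(s3))
})

test_that("CR1 5' extension follows copy support", {
  set.seed(13)
  cfgTool <- simConfig(seed = 13, families = list())
  full <- paste0(rseq(3000), "ATTCTATG")   # 3008 bp, 3'-anchored
  frag <- substr(full, 2009, 3008)         # most copies: last 1000 bp
  mk <- function(s) evolveCopy(s, 0.03, cfgTool)
  pieces <- c(rseq(3000),
              unlist(lapply(1:12, function(i) paste0(mk(frag), rseq(1200)))),
              paste0(mk(full), rseq(1200)), paste0(mk(full), rseq(1200)),
              rseq(3000))
  g <- Biostrings::DNAStringSet(c(chr = paste(pieces, collapse = "")))
  seed3p <- substr(full, 2209, 3008)       # 800-bp 3' seed
  ## only 2 near-full copies: support-3 extension stops near the 1-kb mark
  e3 <- extendFivePrime(seed3p, g, minSupport = 3)
  expect_lt(nchar(e3$consensus), 1250)
  expect_gte(nchar(e3$consensus), 950)
  ## relaxing the support threshold can only lengthen the consensus
  e1 <- extendFivePrime(seed3p, g, minSupport = 1)
  expect_gte(nchar(e1$consensus), nchar(e3$consensus))
})

test_that("CR1 extension recovers near-full length with >= 3 long copies", {
  cfg <- simConfig(genomeLength = 4e5, seed = 23, families = list(
    familySpec("CR", "CR1", totalLength = 2800, copyNumber = 15,
               divergence = 0.04, cr1TruncationMean = 20)))
  sim <- simulateGenome(cfg)
  class(cfg) <- "simConfig"
  seeds <- makeSeedLibrary(simTruth(sim), cfg, cr1SeedLength = 1000)
  r <- curateFamily(as.character(consensusSeqs(seeds)[[1]]),
                    simGenome(sim), name = "CR")
  expect_equal(r$class, "LINE/CR1")
  expect_lte(abs(nchar(r$sequence) - 2800), 20)
})

test_that("curation is invariant to the insertion strand of the copies", {
  fx <- smallSim()
  cur1 <- smallCuration()
  gRC <- Biostrings::reverseComplement(simGenome(fx$sim))
  names(gRC) <- names(simGenome(fx$sim))
  cur2 <- curateLibrary(fx$seeds, gRC)
  for (nm in intersect(names(cur1$library), names(cur2$library))) {
    gi <- globalIdentity(as.character(consensusSeqs(cur1$library)[[nm]]),
                         as.character(consensusSeqs(cur2$library)[[nm]]))
    expect_gt(gi, 0.995)
  }
})

test_that("curated consensuses recover the truth at high identity and length", {
  fx <- smallSim()
  cur <- smallCuration()
  si <- consensusInfo(fx$seeds)
  for (i in seq_len(length(cur$library))) {
    nm <- names(cur$library)[i]
    tf <- si$true_family[match(nm, si$name)]
    rec <- recoveryOf(consensusSeqs(cur$library)[[i]],
                      consensusSeqs(simTruth(fx$sim))[[tf]])
    expect_gte(rec$identity, 0.97)
    expect_gte(rec$coverage, 0.95)
  }
  ## ERV families classified as LTR with the designed TSDs and TG...CA ends
  rep <- cur$report
  expect_equal(rep$class[rep$name == "pred_01"], "LTR")
  expect_equal(rep$tsd[rep$name == "pred_01"], "6")
  expect_equal(rep$tsd[rep$name == "pred_02"], "4")
  expect_equal(rep$end5[rep$name == "pred_01"], "TG")
  expect_equal(rep$end3[rep$name == "pred_01"], "CA")
})
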