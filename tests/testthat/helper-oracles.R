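# Independent oracles used to check implementations.  Each is a direct,
# unoptimised formulation of the quantity being tested and shares no code
# with the package internals.

# Brute-force Smith-Waterman with affine gaps (open+extend charged on the
# first gap base), returning the optimal local score.
bruteSW <- function(a, b, match = 2, mismatch = -3, gapOpen = 5, gapExt = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)     # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt, X[i - 1, j] - gapExt)
    Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt, Y[i, j - 1] - gapExt)
    best <- max(best, M[i, j])
  }
  best
}

# Naive six-frame ORF enumeration: per frame, the first ATG after the
# previous stop opens an ORF that runs to the next stop (or the end).
bruteOrfs <- function(seq, minCodons) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  res <- list()
  for (dir in c(1, -1)) {
    s <- if (dir == 1) seq else rc(seq)
    L <- nchar(s)
    for (off in 0:2) {
      pos <- seq(off + 1, L - 2, by = 3)
      if (!length(pos)) next
      cods <- substring(s, pos, pos + 2)
      open <- NA
      for (ci in seq_along(cods)) {
        if (is.na(open) && cods[ci] == "ATG") open <- ci
        if (!is.na(open) && cods[ci] %in% c("TAA", "TAG", "TGA")) {
          ncod <- ci - open
          if (ncod >= minCodons)
            res[[length(res) + 1]] <- c(dir * (off + 1), ncod)
          open <- NA
        }
      }
      if (!is.na(open)) {
        ncod <- length(cods) - open + 1
        if (ncod >= minCodons)
          res[[length(res) + 1]] <- c(dir * (off + 1), ncod)
      }
    }
  }
  if (!length(res)) return(data.frame(frame = integer(0), codons = integer(0)))
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("frame", "codons")
  df[order(-df$codons, df$frame), ]
}

# Textbook Welch t-test.
bruteWelch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive Wilcoxon signed-rank: enumerate all 2^n sign assignments.
bruteWilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  S <- sum(r)
  wmin <- min(wplus, S - wplus)
  all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
  }, numeric(1))
  p <- (sum(all <= wmin + 1e-9) + sum(all >= S - wmin - 1e-9)) / 2^n
  list(W = wmin, p = min(1, p))
}

# Textbook Kimura 2-parameter distance from transition/transversion counts.
bruteK2P <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# CpG-down-weighted K2P of a copy against its consensus, written directly
# from the definition (transitions at consensus CpG positions get weight w).
bruteWeightedK2P <- function(cons, copy, w = 0.1) {
  a <- strsplit(cons, "")[[1]]; b <- strsplit(copy, "")[[1]]
  cpg <- rep(FALSE, length(a))
  i <- which(a[-length(a)] == "C" & a[-1] == "G")
  cpg[i] <- TRUE; cpg[i + 1] <- TRUE
  mism <- a != b
  ts <- mism & paste0(a, b) %in% c("AG", "GA", "CT", "TC")
  P <- (sum(ts & !cpg) + w * sum(ts & cpg)) / length(a)
  Q <- sum(mism & !ts) / length(a)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Expected substituted fraction of evolveCopy for a given sequence, by a
# per-site probability sum over the same model definition.
expectedSubstFraction <- function(seq, d, kappa = 2, cpgMult = 10) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  alpha <- d * kappa / (kappa + 2)
  beta <- d / (kappa + 2)
  cpg <- rep(FALSE, L)
  i <- which(x[-L] == "C" & x[-1] == "G")
  cpg[i] <- TRUE; cpg[i + 1] <- TRUE
  pts <- ifelse(cpg, pmin(alpha * cpgMult, 1 - 2 * beta), alpha)
  mean(pts + 2 * beta)
}

# the two most prominent local peaks of a landscape table's bp histogram
landscapeModes <- function(lt, binWidth = 1) {
  bins <- seq(0, 50 - binWidth, by = binWidth)
  bp <- vapply(bins, function(b) sum(lt$bp[lt$bin == b]), numeric(1))
  isPeak <- vapply(seq_along(bp), function(i) {
    left <- if (i > 1) bp[i - 1] else -1
    right <- if (i < length(bp)) bp[i + 1] else -1
    bp[i] > 0 && bp[i] >= left && bp[i] >= right
  }, logical(1))
  peaks <- bins[isPeak][order(-bp[isPeak])]
  ## modes must be distinct: successive picks at least 5 bins apart
  sel <- peaks[1]
  for (p in peaks[-1]) {
    if (all(abs(p - sel) >= 5)) { sel <- c(sel, p); break }
  }
  sort(sel)
}

# random DNA string
rseq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

# mutate a sequence at an exact number of substitution sites
mutateExact <- function(s, nmut) {
  x <- strsplit(s, "")[[1]]
  idx <- sample(length(x), nmut)
  for (i in idx) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}
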