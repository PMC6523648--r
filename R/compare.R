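## Cross-genome presence/absence, Dollo branch assignment on a species
## tree, and the two statistical tests used for masking comparisons.

## accept a phylo object, a Newick string or a file path
asPhylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("cannot interpret 'tree' as a phylogeny")
}

#' Branch labels of a rooted tree
#'
#' Every branch is labelled by the sorted tip set of the clade below it,
#' joined with "+"; the branch above the root node is labelled "root".
#' These labels are the vocabulary of [assignBranch()] and
#' [simulateClade()].
#'
#' @param tree phylo / Newick.
#' @return character vector of branch labels (tips, internal clades, root).
#' @export
branchLabels <- function(tree) {
  tree <- asPhylo(tree)
  n <- ape::Ntip(tree)
  labs <- tree$tip.label
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  for (node in internal)
    labs <- c(labs, paste(sort(cladeTips(tree, node)), collapse = "+"))
  c(labs, "root")
}

cladeTips <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, cladeTips, tree = tree))
}

#' Tips descending from a labelled branch
#' @param tree phylo / Newick.
#' @param label a [branchLabels()] label.
#' @return character vector of tip names.
#' @export
branchTips <- function(tree, label) {
  tree <- asPhylo(tree)
  if (label == "root") return(tree$tip.label)
  strsplit(label, "+", fixed = TRUE)[[1]]
}

#' Presence/absence of subfamilies across genomes
#'
#' Every library consensus is searched against every genome (the full
#' reciprocal cross). A subfamily is present in a genome when its best hit
#' passes the E-value cutoff and the support floors (identity and aligned
#' length), and at least `minHits` qualifying hits exist. A family is
#' present wherever any member subfamily is present. Each library is tagged
#' with its source genome; failure of a subfamily to detect itself in its
#' own source genome is a hard error (the search is misconfigured).
#'
#' @param libraries named list of [ConsensusLibrary-class]; names are source
#'   genome names (must appear in `genomes`).
#' @param genomes named list of DNAStringSet (or a named DNAStringSet, one
#'   sequence per genome).
#' @param evalueCutoff maximum approximate E-value (default 1e-10).
#' @param minIdentity,minLength support floors for a qualifying hit.
#' @param minHits qualifying hits required for presence (default 1).
#' @return list: `presence` (logical matrix subfamily x genome), `family`
#'   (character vector: family of each row), `support` (data.frame of best
#'   hits), `sourceGenome` (per subfamily).
#' @export
presenceMatrix <- function(libraries, genomes, evalueCutoff = 1e-10,
                           minIdentity = 0.8, minLength = 80, minHits = 1) {
  if (is(genomes, "DNAStringSet"))
    genomes <- setNames(lapply(seq_along(genomes), function(i) genomes[i]),
                        names(genomes))
  gnames <- names(genomes)
  stopifnot(!is.null(names(libraries)), all(names(libraries) %in% gnames))
  allNames <- character(0); allFam <- character(0); src <- character(0)
  seqs <- character(0)
  for (g in names(libraries)) {
    lib <- libraries[[g]]
    allNames <- c(allNames, names(lib))
    allFam <- c(allFam, as.character(consensusInfo(lib)$family))
    src <- c(src, rep(g, length(lib)))
    seqs <- c(seqs, as.character(consensusSeqs(lib)))
  }
  if (anyDuplicated(allNames)) stop("duplicate subfamily names across libraries")
  pres <- matrix(FALSE, length(allNames), length(gnames),
                 dimnames = list(allNames, gnames))
  supRows <- list()
  for (j in seq_along(gnames)) {
    gen <- genomes[[gnames[j]]]
    empty <- sum(BiocGenerics::width(gen)) == 0
    gChars <- if (!empty)
      lapply(setNames(seq_along(gen), names(gen)), function(i)
        chars(as.character(gen[[i]])))
    for (i in seq_along(allNames)) {
      if (empty) next
      hits <- seedExtendSearch(seqs[i], gen, minScore = 40,
                               queryName = allNames[i],
                               .subjectChars = gChars)
      if (!length(hits)) next
      m <- mcols(hits)
      alnLen <- m$qend - m$qstart + 1
      ok <- m$evalue <= evalueCutoff & m$pid >= minIdentity & alnLen >= minLength
      if (sum(ok) >= minHits) {
        pres[i, j] <- TRUE
        b <- which(ok)[1]
        supRows[[length(supRows) + 1L]] <- data.frame(
          subfamily = allNames[i], genome = gnames[j], score = m$score[b],
          identity = m$pid[b], evalue = m$evalue[b], stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(allNames))
    if (!pres[i, src[i]])
      stop("subfamily ", allNames[i], " failed self-detection in ", src[i])
  list(presence = pres, family = setNames(allFam, allNames),
       support = if (length(supRows)) do.call(rbind, supRows) else NULL,
       sourceGenome = setNames(src, allNames))
}

#' Dollo branch assignment of a presence/absence row
#'
#' Under the single-origin (Dollo) assumption a family was gained on the
#' branch above the most recent common ancestor of all genomes containing
#' it.
#'
#' @param presentTips character vector (or logical named vector) of tips
#'   where the element is present.
#' @param tree phylo / Newick.
#' @return a branch label (see [branchLabels()]).
#' @export
assignBranch <- function(presentTips, tree) {
  tree <- asPhylo(tree)
  if (is.logical(presentTips)) presentTips <- names(presentTips)[presentTips]
  presentTips <- intersect(tree$tip.label, presentTips)
  if (!length(presentTips)) stop("no present tips")
  if (length(presentTips) == 1) return(presentTips)
  node <- ape::getMRCA(tree, presentTips)
  root <- ape::Ntip(tree) + 1L
  if (node == root) return("root")
  paste(sort(cladeTips(tree, node)), collapse = "+")
}

#' Per-branch counts of gained families and subfamilies
#'
#' Each subfamily is assigned to exactly one branch from its presence row;
#' each family to exactly one branch from the union of its subfamilies'
#' rows. Totals over branches equal the numbers of families/subfamilies.
#'
#' @param pm result of [presenceMatrix()].
#' @param tree phylo / Newick.
#' @return data.frame: `branch`, `families`, `subfamilies` (one row per
#'   branch label, zero-filled).
#' @export
branchCounts <- function(pm, tree) {
  tree <- asPhylo(tree)
  labs <- branchLabels(tree)
  subBranch <- vapply(rownames(pm$presence), function(s)
    assignBranch(pm$presence[s, ], tree), character(1))
  fams <- unique(pm$family)
  famBranch <- vapply(fams, function(f) {
    rows <- names(pm$family)[pm$family == f]
    assignBranch(colnames(pm$presence)[colSums(
      pm$presence[rows, , drop = FALSE]) > 0], tree)
  }, character(1))
  data.frame(branch = labs,
             families = as.integer(table(factor(famBranch, labs))),
             subfamilies = as.integer(table(factor(subBranch, labs))),
             stringsAsFactors = FALSE)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (delegates to `stats::t.test`).
#'
#' @param x,y numeric samples (each n >= 2; at least one with nonzero
#'   variance).
#' @return list: `t`, `df`, `p`.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate samples: both variances are zero")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Wilcoxon signed-rank test with midrank ties
#'
#' Zero differences are dropped; |differences| are ranked with midranks for
#' ties; `W = min(W+, W-)`. For n <= `exactMax` (25) the two-sided p-value
#' is exact, computed from the full distribution of the signed rank sum
#' over all sign assignments (a rank-sum convolution over doubled ranks, so
#' midranks stay integral); above that a normal approximation with
#' continuity correction is used.
#'
#' @param d numeric vector of paired differences (or `x`, `y` to take
#'   `x - y`).
#' @param y optional second sample.
#' @param exactMax largest n for which the exact distribution is used.
#' @return list: `W`, `Wplus`, `Wminus`, `n` (nonzero differences), `p`,
#'   `exact` (logical).
#' @export
wilcoxonSignedRank <- function(d, y = NULL, exactMax = 25) {
  if (!is.null(y)) d <- d - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all differences are zero")
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  wminus <- sum(r[d < 0])
  W <- min(wplus, wminus)
  S <- n * (n + 1) / 2
  if (n <= exactMax) {
    ## distribution of 2*W+ over all 2^n sign assignments by convolution
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1); f[1] <- 1    # f[v+1] = #assignments with 2W+ = v
    for (ri in r2) {
      g <- f
      idx <- (ri + 1):(tot + 1)
      g[idx] <- g[idx] + f[idx - ri]
      f <- g
    }
    probs <- f / 2^n
    lo <- sum(probs[seq_len(floor(round(2 * W, 6)) + 1)])
    hi <- sum(probs[(ceiling(round(2 * (S - W), 6)) + 1):(tot + 1)])
    p <- min(1, lo + hi)
    list(W = W, Wplus = wplus, Wminus = wminus, n = n, p = p, exact = TRUE)
  } else {
    mu <- S / 2
    sigma <- sqrt(sum(r^2)) / 2
    z <- (wplus - mu - sign(wplus - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(W = W, Wplus = wplus, Wminus = wminus, n = n, p = p, exact = FALSE)
  }
}
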