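---
title: "Methods: automated TE curation, classification and comparison"
author: "tecur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated TE curation, classification and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`tecur` automates the manual-curation workflow used for in-depth
transposable-element (TE) annotation of bird genomes, where most recent TE
activity comes from endogenous retrovirus (ERV)-like LTR retrotransposons
and CR1 LINEs. The package covers the full arc of such a study: predicted
("seed") consensus sequences are refined against a genome into curated
consensuses; curated elements are classified into ERV superfamilies by
target-site-duplication (TSD) length, into families by the Wicker 80-80-80
rule and into subfamilies at 95% identity; libraries from several species
are compared by reciprocal search and their families placed on branches of
a species tree under a single-origin (Dollo) assumption; repeat landscapes
are computed from Kimura 2-parameter (K2P) divergences with CpG
down-weighting; and ERV copy structure (solo-LTR versus full-length) is
profiled against a pseudo full-length consensus.

Because the real substrates of such studies are large genome assemblies and
licensed repeat libraries, the package ships a synthetic-genome simulator
that generates the study conditions with a complete ground truth. All
quantitative claims made by the test suite and the acceptance script are
claims about this simulator's output; what that does and does not imply for
real data is discussed at the end.

# The simulator

`simulateGenome()` draws a neutral background (i.i.d. bases at a chosen GC
content, 0.42 by default, typical of avian genomes) and inserts TE copies
sequentially at well-separated positions (a jittered grid with a 200-bp
minimum separation; positions are random within slots, which trades exact
uniformity for a guarantee that every requested copy can be placed). The
background is resampled wherever it shares an exact 30-mer with a truth
consensus so that downstream homology search sees no spurious identity.

Element structure follows the biology of the modelled elements:

* **ERV** truth consensuses are `LTR + internal + LTR` with the two LTRs
  identical (as at insertion time) and canonical `TG...CA` termini. Each
  copy duplicates its 4/5/6-bp target site exactly on both sides. A
  configurable fraction of copies is reduced to a solo-LTR — one (evolved)
  LTR flanked by both TSDs — emulating within-element non-allelic
  homologous recombination. The fraction is applied as an exact count
  (`round(p * n)` copies) rather than a Bernoulli draw: the generator's
  purpose is to pin the study conditions, and exact composition removes a
  nuisance source of variance without changing what is being tested.
* **CR1** truth consensuses end in the diagnostic 3' octamer `ATTCTRTG`;
  copies are 5'-truncated by a geometric draw (memoryless decay is the
  simplest model consistent with the 3'-anchored structure of genomic CR1
  copies), capped so at least 200 bp of the 3' end always remains.
* **SINEs** insert full length without TSDs.

Divergence is substitution-only (no indels in this version — a documented
limitation, see below). Each site mutates independently: with divergence
`d` and transition/transversion rate ratio `kappa` (default 2), the
transition probability is `d*kappa/(kappa+2)` and each transversion
`d/(kappa+2)`, so the expected substituted fraction equals `d`. At CpG
dinucleotides (both positions) the transition probability is multiplied by
`cpgMultiplier` (default 10, capped so probabilities stay in `[0,1]`),
reproducing CpG hypermutability. Optionally every remaining G on the
element's sense strand is edited to A with probability `apobecRate`,
emulating APOBEC-mediated C-to-U editing as it appears on the opposite
strand; the simulator fixes the convention that edits are applied to the
sense strand, which is observationally equivalent. Insertion strand is
uniform. A single seed drives every draw; identical configurations
reproduce byte-identical genomes.

The simulator exposes divergence directly rather than an age–divergence
mapping: the analyses downstream are functions of divergence, so time would
only add an arbitrary constant.

`simulateClade()` builds one truth library and inserts each family into
every genome descending from its designated "gain" branch of a rooted
species tree, giving multi-genome data with known presence/absence history.

# Homology search

`seedExtendSearch()` is a self-contained seed-and-extend local aligner
(BLASTn-like scoring: match +2, mismatch −3, gap open −5, gap extend −2;
exact 11-mer seeds, single-hit triggering). Seeds are grouped by diagonal
band and position; each group is extended gaplessly to its maximal-scoring
segment along the best-supported diagonal (restricted to the seed span
plus a 400-bp margin). Because the simulator introduces no indels, gapless
extension is exact for simulated copies; when two well-seeded segments are
collinear but offset — the signature of an indel — the locus is re-aligned
with a gapped local alignment (`Biostrings::pairwiseAlignment`) and the
better result is kept. Overlapping candidates are resolved greedily by
score. On small instances the reported top score equals full
Smith–Waterman whenever the optimal alignment contains an exact seed and is
either gap-free or split into seeded collinear segments; this completeness
condition is exercised by the test suite against a brute-force DP oracle.

E-values use the ungapped Karlin–Altschul form with lambda solved for the
scoring scheme at uniform composition and K fixed at 0.41. They are used
only as thresholds (1e-10 for reciprocal presence, 1e-7 for coverage
profiling); no quantitative claim rests on them.

`maskGenome()` searches every library consensus, keeps hits scoring at
least 225 and resolves overlaps greedily by score, trimming lower-scoring
hits at overlap boundaries and discarding fragments under 20 bp, with
alignment slices, scores and identities recomputed for trimmed fragments.

# Curation

`curateFamily()` automates the by-eye curation loop:

1. **Collect** the 20 best hits (deduplicated by genomic locus) with 2-kb
   flanks, reverse-complementing minus-strand rows into consensus
   orientation.
2. **Anchor** all rows in the seed consensus coordinate frame using each
   hit's own alignment; flanks are placed by coordinate offset. This
   replaces a de-novo multiple alignment: for substitution-only copies the
   anchored frame is exactly the alignment an MSA program would produce,
   at a small fraction of the cost. (With real, indel-containing copies an
   external MSA could be substituted behind the same
   `CurationAlignment` contract.)
3. **Detect boundaries.** Within the element, rows agree; in the flanks
   they are unrelated. The core is the maximal run of columns where a
   20-column sliding window keeps at least 70% of row pairs in agreement,
   with edges refined column-wise (tolerating up to two consecutive
   low-agreement columns — CpG hotspots sit right at element edges often
   enough that a single hypermutable site would otherwise clip the
   boundary). Boundaries may then extend *through* flank space while at
   least `min(3, rows)` rows stay ≥80% identical to the window majority;
   the majority is computed over the rows that supported the previous
   window, mirroring a curator following the copies that keep aligning.
   This recovers element sequence beyond a truncated seed, and exposes the
   degenerate case of copies inserted into identical flanking sequence
   (near-unanimous extension), which is flagged `ambiguous-boundary`.
4. **Build the consensus** by per-column majority over the characters that
   hit alignments actually placed (so solo-LTR rows vote only across the
   LTR span and cannot delete the internal region); a gap wins a column
   (dropping it) only above 50%; ties break in the fixed order A<C<G<T so
   consensuses are byte-stable. Hypermutable CpG sites are restored as
   `CG` when either (a) CG and its deamination product are the two
   dominant dinucleotide patterns and CG is carried by at least two rows
   and a quarter of the rows, or (b) CG, TG and CA all co-occur (TG and CA
   cannot both arise from a non-CpG ancestor). The quarter floor in (a)
   keeps sporadic transitions at ordinary TpG/CpA sites from being
   miscalled; rule (b) carries the restoration through high divergence,
   where deamination products outnumber the ancestral state.
5. **Classify structurally.** A consensus carrying the CR1 octamer
   `ATTCTRTG` in its final 60 bp is treated as a CR1: it is extended
   5'-ward (`extendFivePrime`) while at least three rows remain ≥80%
   identical to the window majority, re-collecting hits when the available
   flank is exhausted, and finally trimmed so the octamer ends the
   consensus. Otherwise TSDs are detected per copy around the
   genomic element interval of every row spanning the core (each boundary
   slid ±2 bp; the per-copy call is the maximal k at the smallest offset —
   without the maximal-k rule every 6-bp TSD would also be reported at 5
   via a shifted sub-k-mer). The family-level TSD set keeps lengths
   carried by at least two calls and a quarter of the calls, so a genuine
   mixed-TSD family is reported as ambiguous while stray chance matches
   are not. LTR termini are snapped to `TG...CA` within 3 bp when present.

`curateLibrary()` applies `selectForCuration()` first (drop predictions
whose best local alignment to a known consensus reaches 95% identity — the
"more than 5% diverged" rule, with the boundary case excluded) and then
curates every seed, reporting uncuratable elements (fewer than two hits, or
no homologous core) with reasons.

# Classification

Superfamily follows TSD length (4 bp → ERV1, 6 bp → ERV2, 5 bp → ERV3);
several supported lengths give an explicit `ambiguous` call. Families
follow the 80-80-80 rule: local alignments with >80% identity covering
>80% of the shorter consensus for ≥80 aligned bp. The shorter-sequence
denominator is deliberate, so a solo-LTR-derived consensus can join its
family's full-length consensus. Both directions are evaluated and OR-ed,
making the decision symmetric. New consensuses are tested against the
reference library first, then against already-accepted novel families, the
best-identity qualifying match winning. Subfamilies are single-linkage
clusters at ≥95% global-alignment identity with gaps counted as
mismatches (single linkage mirrors the reading "merge if ≥95% similar to
any member"; complete linkage would split chains and is noted as the
alternative). Naming is deterministic: new families get
`<species><LTR><superfamily letter><ordinal>` names (K for ERV2, L for
ERV3, none for ERV1), heterospecific subfamilies append `_<species>`.
CR1 subfamilies use the same 95% rule rather than a maximum-likelihood
phylogeny; this is a documented simplification.

# Comparison across genomes

`presenceMatrix()` searches every subfamily consensus against every genome
(the full reciprocal cross). Presence requires the approximate E-value
cutoff (1e-10) plus support floors — identity ≥0.8 over ≥80 aligned bp and
at least one qualifying hit by default; the floors are configurable because
short spurious hits would otherwise satisfy a bare E-value threshold.
A subfamily failing to detect itself in its source genome is a hard error.
`assignBranch()` places each family above the most recent common ancestor
of the genomes containing it (Dollo parsimony; no probabilistic ancestral
reconstruction), and `branchCounts()` tallies families and subfamilies per
branch, each counted exactly once.

`welchT()` wraps the unequal-variance t-test; `wilcoxonSignedRank()`
implements the signed-rank test with midrank ties, zero-difference removal
and an exact two-sided p for up to 25 nonzero differences via a rank-sum
convolution over doubled ranks (ranks are doubled so midranks stay
integral), with a continuity-corrected normal approximation above. The
exact path is implemented here because the base-R test cannot produce
exact p-values in the presence of ties.

# Landscapes and overlap statistics

`kimura2p()` computes `K = -1/2 ln((1-2P-Q) sqrt(1-2Q))` over columns
without gaps or Ns, where transitions at consensus-CpG columns contribute
weight `cpgWeight` (default 0.1) instead of 1 — down-weighting rather than
excluding hypermutable sites. With `cpgWeight = 1` this is the textbook
K2P estimator (verified to 1e-12 against the closed form). A non-positive
logarithm argument returns a saturation sentinel of 0.5, flagged via an
attribute and binned into the last landscape bin. `landscapeTable()` bins
each resolved hit's bp by its K2P distance in 1-percentage-point bins over
0–50%, per TE class; `summaryTable()` emits the standard per-class
copies/bp/% summary. `overlapRatio()` counts test hits sharing ≥1 bp with
any baseline hit, strand-agnostic — the intersect semantics used for
masking-competition comparisons.

# ERV copy structure

`buildPseudoFullLength()` concatenates LTR + internal + LTR with a region
map. `coverageProfile()` maps all hits at E ≤ 1e-7 onto consensus
coordinates, accumulates per-position coverage and flags hits spanning
≥90% of the consensus as full-length (the printed-figure notion of
"spanning a majority of the consensus", formalised here as 90%).
`classifyCopyStructure()` merges hits within 100 bp into loci (fragmented
diverged copies re-join) and calls a locus solo-LTR when ≥80% of its
mapped bp falls in LTR regions and it is at most 1.5 LTR lengths long;
full-length when it covers ≥90% of the consensus; truncated otherwise.
`findOrfs()` scans all six frames for `ATG`-to-stop runs of at least
`minCodons` codons, flagging ORFs still open at the sequence end.

# Numerical and design choices

* Coordinates are 1-based closed (`IRanges` convention) everywhere inside
  the package; conversion happens only in the BED writer/reader (0-based
  half-open) and GFF3 export. A single internal convention avoids
  off-by-one drift.
* The search scoring constants, seed length (11), masking score floor
  (225), hit-collection defaults (20 hits, 2-kb flanks), boundary-window
  parameters (20 columns, 70% pair agreement), CR1 support threshold (3
  rows at 80%), CpG weight (0.1) and structure thresholds (90%
  full-length, 80% LTR fraction, 100-bp merge gap) are all exposed as
  function arguments with the defaults stated here.
* Randomness: every simulator entry point seeds R's RNG from its
  configuration; derived seeds for multi-genome simulations stay below
  2^31.
* Problem sizes used by the test suite and acceptance script: the main
  study genome is 5 Mb with 12 families (~440 copies, ~1.1 Mb of TE
  sequence); burst, solo-LTR and clade analyses use 0.25–2.5 Mb genomes.
  These sizes keep every stage's behaviour measurable (dozens of copies
  per family) while completing in minutes on one CPU.

# What the synthetic tests do and do not show

The simulator reproduces the structural signals the pipeline exploits
(TSDs, LTR termini, solo-LTR formation, 3'-anchored CR1 decay, CpG
hypermutation, strand symmetry) under a substitution-only, neutral,
non-nested insertion model. Passing tests therefore demonstrate that the
algorithms correctly invert *that* generative model at realistic sizes and
divergences. Real genomes additionally contain indels (the anchored
alignment would need an external MSA engine), nested and tandem
insertions, segmental duplications, assembly gaps and collapsed repeats,
diverged subfamily structure within families, and non-neutral base
composition — none of which are modelled. Consequently, quantitative
recovery rates measured here are upper bounds on real-data performance,
and the masking-competition contrast (shared families overlap the baseline
annotation at a ratio near 1, novel families near 0) should be read as a
qualitative reproduction of the phenomenon, not a calibrated estimate.

# Reproducing the numbers

`scripts/acceptance.R --seed N --out results.json` regenerates the study
design from scratch (simulation, curation, classification, landscapes,
masking competition, clade comparison, copy-structure profiling,
statistics) and writes every headline quantity as JSON. The test suite
(`tests/testthat`) runs the same checks with fixed seeds plus
property-style checks against brute-force oracles (Smith–Waterman DP,
exhaustive sign enumeration, closed-form K2P, naive ORF enumeration).
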