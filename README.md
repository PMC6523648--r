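# tecur

Automated curation, classification and comparative annotation of
transposable elements (TEs), centred on the element biology of bird
genomes: endogenous retrovirus (ERV)-like LTR retrotransposons and CR1
LINEs.

## The problem

In-depth TE annotation of a genome starts from de-novo predicted consensus
sequences, which are fragmentary, redundant and unclassified. Manual
curation turns them into a usable library: for each prediction, the best
genomic hits are collected with flanks and aligned; a majority-rule
consensus is rebuilt (restoring hypermutable CpG sites as `5'-CG-3'`);
element boundaries are fixed using target site duplications (TSDs), the
canonical `5'-TG...CA-3'` LTR termini and the CR1 3' octamer
`5'-ATTCTRTG-3'`; CR1 consensuses are extended 5'-ward while at least
three copies keep supporting the alignment. Curated elements are then
classified — ERV superfamily by TSD length (4 bp → ERV1, 6 bp → ERV2,
5 bp → ERV3), family by the Wicker 80-80-80 rule (>80% identity over >80%
of the shorter consensus for ≥80 bp), subfamily at ≥95% consensus
identity — compared across genomes by reciprocal search with Dollo branch
assignment on a species tree, and summarised as repeat landscapes: per-copy
Kimura 2-parameter distance

    K = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]

with transitions at consensus CpG sites down-weighted (weight 0.1) instead
of excluded. ERV copy structure (solo-LTR vs full-length, the product of
within-element non-allelic homologous recombination) is profiled against a
pseudo full-length `LTR + internal + LTR` consensus.

`tecur` implements this whole arc as tested, scriptable R functions, with
a self-contained seed-and-extend homology search (no external aligner
needed) and a synthetic-genome simulator that produces ERV/CR1/SINE
insertions with exact TSDs, solo-LTR formation, geometric 5' truncation,
transition/transversion-biased divergence, CpG hypermutation and optional
APOBEC-style G→A editing — plus the full ground truth, so every stage is
verifiable.

## Worked example

```r
library(tecur)

cfg <- simConfig(genomeLength = 5e5, seed = 11, families = list(
  familySpec("ERV_A", "ERV", ltrLength = 300, internalLength = 2000,
             tsdLength = 6, copyNumber = 25, divergence = 0.05,
             soloLtrProb = 0.4),
  familySpec("CR1_A", "CR1", totalLength = 3500, copyNumber = 30,
             divergence = 0.06, cr1TruncationMean = 800)))
sim <- simulateGenome(cfg)
sim
#> TESimulation: 1 sequence(s), 626467 bp; 55 inserted TE copies from 2 families
#>  structures: full_length:15 solo_LTR:10 truncated:30

seeds <- makeSeedLibrary(simTruth(sim), cfg)   # emulated de-novo predictions
cur <- curateLibrary(seeds, simGenome(sim))
cur$report[, c("name", "class", "length", "tsd", "end5", "end3")]
#>      name    class length tsd end5 end3
#> 1 pred_01      LTR   2600   6   TG   CA
#> 2 pred_02 LINE/CR1   3379      <NA> <NA>
```

The curated ERV consensus is full length (2600 bp = 300 + 2000 + 300) with
canonical `TG...CA` termini and the designed 6-bp TSD, which classifies it
to superfamily ERV2; the CR1 consensus was rebuilt 3'-anchored and extended
5'-ward to 3379 of 3500 bp — extension stops where fewer than three copies
still support the alignment, exactly as the copy-truncation distribution
dictates.

Masking and landscape:

```r
track <- maskGenome(simTruth(sim), simGenome(sim))
summaryTable(track)
#>                         type copies     bp   pct
#> 1                       SINE      0      0  0.00
#> 2                       LINE     30  84320 13.46
#> 3                        LTR     25  41981  6.70
#> 4                        DNA      0      0  0.00
#> 5               Unclassified      0      0  0.00
#> 6 Total interspersed repeats     55 126301 20.16
```

`landscapeTable(track)` bins those bp by per-copy K2P divergence;
`coverageProfile()` + `classifyCopyStructure()` recover solo-LTR versus
full-length status; `presenceMatrix()` + `branchCounts()` place families
on a species tree.

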