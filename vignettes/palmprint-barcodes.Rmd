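---
title: "Palmprint barcodes: motif-based RdRP detection, scoring and clustering"
author: "palmprintR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Palmprint barcodes: motif-based RdRP detection, scoring and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmprintR)
```

## The barcode and the model

RNA viruses are increasingly known only from sequence, and their
hallmark gene — the RNA-dependent RNA polymerase (RdRP) — is the
natural basis for classification. The palm sub-domain of RdRP (and of
the related reverse transcriptases, RTs) carries three short catalytic
motifs, conventionally A, B and C: A and C contain essential aspartate
residues that coordinate the catalytic cation, and B contains a nearly
invariant glycine. In most lineages the motifs occur in the primary
sequence in canonical A–B–C order; several independent lineages carry
a circular permutation that places them in C–A–B order. The
*palmprint* is the minimal segment containing all letters of the three
motifs: from the first letter of A to the last letter of C
(canonical), or from the first letter of C to the last letter of B
(permuted). At roughly 100 aa it is short enough to survive in
fragmented metagenomic assemblies and long enough to carry usable
phylogenetic signal, and its motif-delimited boundaries make pairwise
*global* alignment identities commensurate across queries — the
property that underpins OTU clustering.

### Position-specific scoring matrices

Each motif of each polymerase group is modelled as an ungapped PSSM
built from a seed multiple alignment. Per column $i$ and amino acid
$a$, the observed frequency $f_{ia}$ (gap rows excluded from the
denominator — gaps are treated as missing data, since curated seeds
occasionally carry them even though motif indels are strongly
suppressed) is smoothed with the background distribution $b$ by a
pseudocount mixture

$$p_{ia} = (1 - w)\, f_{ia} + w\, b_a, \qquad
  S[i, a] = \log_2 \frac{p_{ia}}{b_a},$$

and a window of query $Q$ starting at $s$ scores
$\sum_{i=1}^{L} S[i, Q_{s+i}]$. Design choices here that the
literature leaves open, all configurable:

* **Pseudocount semantics.** "Pseudocount frequency 0.1" is read as a
  0.1-weight *mixture* with the background rather than +0.1 raw
  counts: a mixture keeps every column a proper probability
  distribution regardless of the number of seed rows, and the phrase
  names a frequency. `buildPSSM(pseudocount = )` exposes the weight.
* **Log base.** Scores are bits (log base 2). The score-ledger
  constants (2, 5, 20) are interpreted in the shipped score units, so
  the system is self-consistent whatever the original convention was.
* **Background.** The BLOSUM62 marginal amino-acid frequencies,
  hard-coded as `blosum62Background()` (20 values summing to 1).
* **Score floor.** With $w = 0$ an unobserved residue would score
  $-\infty$; it is floored at $-20$ bits to keep arithmetic finite.
  Unreachable at the default $w = 0.1$.
* **Residue conventions.** Ambiguity codes (X, B, Z, J, U, O) score 0
  bits — they neither support nor refute a motif. A stop codon scores
  $-100$, vetoing any window containing it. Frames are *not* split at
  stops: palmprints frequently span sequencing errors in metagenomic
  contigs, and splitting would silently fragment them.

### Detection and the heuristic score ledger

For an amino-acid query (each of the six reading frames of a
nucleotide query, standard genetic code), every PSSM of every set is
placed at its best-scoring position, ties going to the leftmost
window. The placements must be ordered A–B–C or C–A–B without overlap;
anything else rejects the set for that query. The candidate score
starts from the raw sum of the three motif scores and applies the
ledger held in a `HeuristicConfig`:

| rule | default | effect |
|---|---|---|
| `minMotifScore` | 2 bits | any motif below it: candidate rejected |
| `v1Min` / `v1Penalty` | 35 aa / 5 bits | short V1 penalised |
| `v1Max` | 120 aa | V1 above band: −5 bits |
| `v2Min`–`v2Max` | 15–90 aa | V2 out of band: −5 bits |
| `ppMinLen`–`ppMaxLen` | 70–160 aa | palmprint out of band: −5 bits |
| `highConfidenceThreshold` | 20 bits | confidence call on the adjusted score |

The first two rules are the published ones; the band penalties
generalise the same expert judgement — observed V1/V2 and palmprint
length distributions are tightly constrained by structure — with
defaults bracketing the ~100 aa palmprint. They are configuration, not
hidden constants. A V1 below `v1Min` incurs only `v1Penalty` (not a
second band penalty); V1 above `v1Max`, V2 outside its band and an
out-of-band palmprint length each cost `outOfRangePenalty`.

The set with the highest *raw* motif score sum among surviving
candidates wins (ties by group name); the adjusted score is used only
for the confidence call, with candidates below the threshold reported
as `confidence = "low"` rather than dropped, so that threshold sweeps
remain possible. For nucleotide queries the best frame is chosen by
adjusted score (ties in frame order +1, +2, +3, −1, −2, −3), and hits
carry forward-strand nucleotide coordinates. One hit per query is
reported — the global best; a contig containing two RdRPs yields only
the stronger one (a known limitation).

By default each motif contributes only its single best placement,
matching the published algorithm description; `topK > 1` switches to
an exhaustive mode that evaluates every ordered, non-overlapping
combination of the top-k placements per motif, which can rescue
queries where the independent optima collide.

All coordinates, internal and reported, are 1-based inclusive — the
natural R convention; nucleotide coordinates are reported on the
forward strand with an explicit strand field.

## Identity, clustering and the species threshold

Because palmprints are same-scale segments, divergence is measured on
*global* alignments: Needleman–Wunsch with BLOSUM62, affine gap cost
$11 + k$ for a gap of length $k$, end gaps penalised. Percent identity
is $100 \cdot \text{matches} / \text{columns}$ with **all** alignment
columns (including end gaps) in the denominator; other tools often
divide by the shorter sequence length, which inflates identities of
length-discordant pairs. Co-optimal alignments exist, especially
between unrelated sequences, and would make identity depend on
argument order; the implementation therefore aligns every pair in a
canonical orientation (lexicographically smaller sequence as the DP
pattern), making identity exactly symmetric.

Species-like OTUs come from greedy centroid clustering: records in
length-descending order (ties by id) either join the first
previously-founded centroid at or above the identity threshold or
found a new cluster — a deterministic stand-in for the referenced
greedy clustering tool, whose internal candidate order is not
published. The default threshold is 90%, the level at which lumping
and splitting of recognised species balance. `tuneThreshold()`
reproduces that calibration on any labelled collection: per threshold
it counts species split over multiple OTUs, lumped with other species,
both, or pure. `selectBalancedThreshold()` picks the threshold whose
cluster count best matches the species count; ties are broken by the
larger pure count and then by the median of the tied thresholds —
cluster counts typically plateau over a range of thresholds, and the
plateau midpoint is the choice most robust to resampling. Identity
bands for search hits (`rankOfIdentity()`) are right-closed downward:
exactly 90 is genus-like (the species band is a strict >90), and the
70 and 45 edges are resolved the same way.

## What the synthetic generator does and does not emulate

`makePositive()` emits flank + motifs (sampled column-wise from a
PSSM's implied probabilities; temperature 0 gives the consensus) with
background-sampled V1/V2 between them, recording every planted
coordinate. `makeDecoy()` draws iid residues from the background.
`makeSpeciesPopulation()` builds centroids roughly `betweenIdentity`
percent identical (verified by global alignment during construction,
redrawn on violation) with members mutated to `withinIdentity` ± 2
percentage points by substitutions only — palmprint indels are rare
enough that a substitution-only model is the realistic default.
`encodeNt()` reverse-translates with uniformly sampled synonymous
codons into any frame and strand.

These fixtures emulate the *layout* of real palm domains (conserved
motifs, variable in-band spacers, six-frame embedding) but not their
evolutionary texture: real motifs deviate from seed consensus in
correlated ways, real V regions are compositionally biased rather than
background-iid, and real negatives (RTs, endogenous viral elements,
disordered proteins) are far harder than iid decoys. Passing the
planted-recovery and decoy suites therefore demonstrates correctness
of the machinery — exact scoring, ordering, coordinate arithmetic and
thresholds — not field sensitivity/specificity, which depend on the
quality of the trained PSSM sets supplied by the user. The shipped
`examplePssmSets()` are synthetic demonstrations with the
field-typical shape (motifs of 12–15 aa, invariant catalytic
aspartates and glycine) and make no claim to reproduce any curated,
trained motif models.

## Numerical choices and degenerate inputs

* Window-score summation is left-to-right per column in both the C
  kernel and the reference definition, so tests can require *exact*
  equality.
* `bestHit()` ties resolve to the smallest start; top-k placements use
  a stable sort, so equal scores keep left-to-right order.
* Nucleotide queries shorter than three times the smallest motif
  triple are errors (no palmprint could fit); amino-acid frames
  shorter than a motif simply lack that motif, which rejects the set.
* Empty FASTA files, duplicate ids and out-of-alphabet residues are
  errors naming the record and position. U is normalised to T, case is
  folded, and alignment gaps are stripped from amino-acid queries on
  ingest.
* The random-nucleotide decoy stream is a deterministic function of
  the seed alone; chunked scanning overlaps consecutive chunks by
  twice the maximum palmprint nucleotide length (2 × 3 × `ppMaxLen`)
  and deduplicates by global coordinates, so the reported hit set is
  invariant to the chunk length. The stream model is iid uniform
  A/C/G/T by default with an optional composition bias, since the
  composition of the original decoy stream is unstated.

## Problem sizes used by the test and acceptance suites

The suites exercise: exact-score equivalence on 1,000 random
(PSSM, frame, start) triples; planted-motif recovery on 1,000
consensus-motif positives with in-band V lengths (both motif orders);
frame/strand consistency on 100 positives across all six encodings;
specificity on 10,000 background decoys of length 500 and a 10^6-base
random nucleotide stream; and clustering recovery plus the 97–85%
threshold sweep on a planted population of 20 species × 10 members
(within ≈95%, between ≈70% identity). These sizes give stable
statistics for every property asserted while keeping a full run
comfortably interactive.

## Known limitations

* One hit per query; multiple RdRPs on one contig are not enumerated.
* Sensitivity to genuinely novel groups is bounded by the supplied
  PSSM sets; the package ships no trained models.
* The greedy clusterer's result depends on its documented processing
  order; it is deterministic but not order-free.
* Reference search uses the same global aligner as clustering for
  internal consistency; identities for partial-length queries will
  differ from local-alignment search tools.
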