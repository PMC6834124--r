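---
title: "mirtriplex: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtriplex: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtriplex)
```

mirtriplex predicts functional properties of short candidate microRNAs
(20–22 nt) against the 600-bp 5'-flanking promoter regions of their target
genes: secondary-structure stability, promoter CpG-island content,
triplex-forming potential against duplex DNA, and the position of the
targets in a stage-specific somatic-event network. This vignette explains
the models behind each stage, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the design
decisions that were genuinely open.

## Coordinates and sequence handling

All internal coordinates are 0-based half-open; BED input is native and
GFF3 is converted on import (−1 on start). The TSS is the first
transcribed base and the upstream promoter window excludes it: a
plus-strand promoter is `genome[tss − 600, tss)`, a minus-strand promoter
the reverse complement of `genome[tss + 1, tss + 601)`, both read 5'→3' on
the gene's own strand. Windows truncated at a contig edge are returned
shorter with a warning rather than erroring — a silent error would drop a
gene from every downstream table, whereas a short promoter is still
analyzable. `N` bases are tolerated in promoters; any CpG window or
triplex register touching an `N` is skipped rather than scored. Multiple
transcripts per gene are out of scope: the annotation row is taken as
given.

## RNA secondary structure

The folding stage is a Zuker-style dynamic program over pseudoknot-free
structures with hairpin, stack, bulge, internal-loop and affine multiloop
terms, followed by a threshold-complete traceback that enumerates *every*
structure within `energy_window` kcal/mol of the minimum free energy
(deduplicated by pair set; ties in the final ordering broken
lexicographically by dot-bracket string under byte order, so results are
locale-independent). At 20–22 nt this complete enumeration is cheap and
sidesteps the sampling bias of stochastic backtracking.

The energy model ships as versioned TSV tables
(`inst/extdata/nn_stacks.tsv`, `loop_penalties.tsv`):

* 6×6 pair-on-pair nearest-neighbour stack table over
  {AU, UA, CG, GC, GU, UG}, rotationally symmetric. Watson–Crick entries
  follow the published nearest-neighbour free energies at 37 °C (e.g.
  5'GC/3'CG = −3.42 kcal/mol); GU-wobble entries are package defaults of
  plausible magnitude. Correctness of the *algorithm* is defined against a
  brute-force enumeration oracle that scores structures by explicit loop
  decomposition under the identical tables, so the conclusions of the test
  suite do not depend on the calibration of any individual entry.
* Loop initiation penalties for hairpins (size 3–9), bulges (1–6) and
  internal loops (2–6), extrapolated beyond the tabulated range with the
  Jacobson–Stockmayer term `ΔG(n) = ΔG(n_max) + 1.75·RT·ln(n/n_max)`. The
  hairpin table is deliberately monotone non-decreasing in loop size:
  experimentally measured tables dip at size 6, which lets a helix slide
  toward a larger loop at equal stack energy — physically defensible but a
  pathological tie-breaker for planted-structure recovery, and not worth
  the ambiguity in a package-default model.
* Multiloop affine parameters a = 3.4 (closing), b = 0.4 (per branch),
  c = 0 (per unpaired base); terminal AU/GU helix-end penalty
  0.45 kcal/mol, applied once per helix end (a lone AU pair pays twice).
  Minimum hairpin loop 3 nt; GU pairs allowed; lone pairs are not
  prohibited. The open structure has energy 0, so the MFE is never
  positive; suboptimal structures above 0 are legal and are reported when
  the window reaches them.

`energy_window` defaults to 5 % of |MFE| with a floor of 1.0 kcal/mol,
mirroring the percent-of-MFE convention of classical MFE servers while
keeping a usable window for weakly folding 22-mers; the reported
`energy_window` column plays the role of the δG "plot profile" increment
in the structure-count table. The dot plot counts, for every pair (i, j),
how many retained structures contain it — the superposition of all optimal
and suboptimal foldings. Stability ranking orders microRNAs by ascending
MFE (ties by id): lower free energy, more stable molecule.

## CpG islands

For each 200-bp window advanced at 1-bp steps (both configurable):
`GC% = 100·(#C + #G)/N` and `Obs/Exp CpG = #CpG · N / (#C · #G)`, with
`#CpG` the *overlapping* count of CG dimers — the statistic measures
dinucleotide enrichment, and overlapping counting is the standard reading
(a window of `CGCGCG…` should count every CG). Windows with `#C = 0` or
`#G = 0` take Obs/Exp = 0 by convention: they cannot qualify as island
windows and the per-gene summaries stay total. A window qualifies when
GC% > 50 *and* Obs/Exp > 0.6, both strict; overlapping or adjacent
qualifying windows merge into maximal island ranges, so every island spans
at least one window (> 200 bp at defaults) — the three classical island
characteristics. Summaries report min/max GC% and Obs/Exp over all
non-skipped windows at full precision internally and two decimals in the
written tables.

## Triplex search

The microRNA is treated as a triplex-forming third strand laid ungapped
and full-length into the major groove of the promoter duplex. Canonical
triplets are U·A:T, C·G:C, G·G:C, A·A:T for the parallel (Hoogsteen,
"direct") code and A·A:T, U·A:T, G·G:C for the antiparallel
(reverse-Hoogsteen, "indirect") code; C·G:C requires protonation in
reality, and is admitted without pH modelling. Both duplex strands are
tested as the purine-carrying strand, and coordinates are always reported
on the given promoter strand. Per-triplet contributions are configuration,
defaulting to weight +8 / energy −8 for canonical and −8 / +4 otherwise —
calibrated so that a perfect 22-triplet register scores 176 > 140 with
energy −176 < −140, registers with up to two non-canonical triplets still
pass (144, −152), and three or more fail (128): the retention thresholds
(score > 140, energy < −140, both strict and jointly applied) then
separate near-perfect registers from everything else. Registers are
ungapped because 20–22-nt third strands leave no room for bulged triplex
geometry at these thresholds.

Hits are graded against the best-register scores of N = 1000 seeded
dinucleotide-preserving shuffles (Altschul–Erickson Euler-walk shuffle,
written in-package since no installed R package provides it) of the third
strand against the same duplex: grade 5 at or above the 99th percentile,
then 4/3/2 at the 95th/90th/75th, else 1. The percentile of a hit is the
fraction of background scores ≤ the hit score, so a hit equalling a
constant background is grade 5 (it is at the 100th percentile of that
sample). Dinucleotide-preserving shuffling controls for both base and
dimer composition, which dominate register scores for short strands.

The summary matrix renders `+n` for direct hits, `-n` for indirect, `0`
for none and `-a/+b` for both, and keeps strand and orientation as
separate hit columns rather than conflating them.

## Event networks

Somatic-event tables (gene, stage, variant type, optional
`antecedent_of` links) and interaction edge lists (gene pair, kind,
weight) are consumed as TSV exports; live database queries are out of
scope. Stage and variant vocabularies are closed sets
(early/late/relapse/metastatic/drug-induced/drug-resistance;
mutation/methylation/LOH/CNV-loss/CNV-gain/alteration) and unknown tokens
are hard errors — silent acceptance of a typo would corrupt every
downstream stage query. Temporal paths are shortest directed paths by BFS
with lexicographically ordered neighbour expansion, so tie-breaking is
deterministic. Interaction composition is the percentage of total edge
*weight* per kind (unit weights when absent), summing to 100 within 1e−9.
Composition figures of the kind the demo emulates are often reported
rounded and need not sum to exactly 100; the demo edge list is built from
integer weights that yield an exactly consistent set
(43.83 / 26.28 / 14.23 / 10.14 / 3.89 / 1.63). Networks export as Cytoscape SIF
(including isolated nodes as single-column lines) and as GraphML with
stage/variant/target attributes that round-trip through `import_network`.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (seed, parameters) and each returns a
`truth` record sufficient to score recovery without re-deriving it.

* `make_hairpin_rna` plants a stem of reverse-complementary pairs around
  an A-loop. The 5' flank is poly-A — inert by construction, it can pair
  with nothing else in the molecule — and the 3' flank is AG-random with
  no two adjacent Gs, so flank Gs can form only lone, unfavourable pairs
  and the planted stem remains the only stable helix. The flank asymmetry
  (A-rich 5', G-bearing 3') additionally prevents the molecule from
  reading as a triplex register in the reversed orientation when the same
  RNA seeds a triplex fixture.
* `make_cpg_promoter` samples island and background from first-order
  Markov chains whose C→G transition is scaled to the requested Obs/Exp
  and whose stationary composition matches the requested GC%; the island
  draw is re-sampled deterministically until realized composition is
  within 4 GC points and 0.15 Obs/Exp of the request. Background defaults
  (35 % GC, Obs/Exp 0.3) sit well below the island thresholds.
* `make_triplex_promoter` writes the all-canonical purine tract for the
  given third strand at each requested position, flanked by 3-bp
  pyrimidine spacers inside pyrimidine-biased random background
  (A/C/G/T at 0.2/0.3/0.2/0.3). The spacers guarantee that any register
  shifted three or more positions off a planted site crosses pyrimidine
  duplex bases, which no triplet code accepts; the remaining shifted and
  cross-orientation reads (offsets −2…2) touch only tract and spacer
  bases, so the generator checks them exhaustively and *rejects* third
  strands whose planted tract would be ambiguous (e.g. a poly-A strand,
  canonical in both orientations, or a strand whose purine pattern is
  nearly symmetric under reversal). This keeps truth records exact without
  ever consulting the scanner.
* `make_event_table` / `make_edge_list` encode the CRC staging facts the
  pipeline should recover (APC early; GNAS metastatic; KRAS
  early/late/drug-resistance; the chains APC→TP53→TCF7L2 and
  CASP8→KRAS→PIK3CA) plus seeded filler genes in a reserved `FG` namespace.

What passing tests therefore show: the algorithms recover exactly what the
models define, at the stated thresholds, on sequences whose composition is
controlled. What they do not show: real promoters have repeat structure,
CpG-island shores, and base-composition autocorrelation that no
first-order chain reproduces; real microRNAs are not planted hairpins; and
the triplet weight tables are calibrations, not measurements. Results on
real data inherit the quality of those inputs.

## Numerical choices

* Energies are doubles; enumeration pruning and retention use a 1e−9
  slack so floating-point drift never drops a boundary structure.
* Suboptimal structures sort by (energy, dot-bracket) under radix order.
* Degenerate inputs: sequences with no pairable positions fold to the
  open structure at 0.0; an empty FASTA, a promoter shorter than the CpG
  window, a third strand longer than its duplex, an empty node set at
  export, and unknown vocabulary tokens are all immediate errors naming
  the offending input.
* The whole pipeline writes no timestamps, and every report carries the
  seed and a config hash, so identical configurations are byte-identical
  across runs.

## Problem sizes in the test suite

The folding oracle is exercised exhaustively over *all* RNA sequences of
length ≤ 7 (21,844 sequences — every sequence that can pair at all under
the minimum-loop constraint) and over seeded random samples at lengths
8–16; suboptimal enumeration is checked against full enumeration at length
12 and for window-monotonicity on 100 random 22-mers. CpG statistics are
recounted naively on 1,000 random 200-mers; island and triplex recovery
each run 100 seeded fixtures; grading uses a 1,000-shuffle background.
These sizes were chosen so every brute-force comparison remains exact
while the full suite stays interactive (about two minutes).

## Known limitations

* No pseudoknots, no partition-function pair probabilities, no tertiary
  structure; energies need not match any specific published folding
  server since the tables are package defaults.
* Triplex scoring is additive and ungapped; no pH, divalent-cation or
  bulged-triplex modelling.
* CpG methylation state is not predicted — island presence is a sequence
  property only.
* Event networks are only as good as the exported tables; the package
  performs no statistical inference on them.
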