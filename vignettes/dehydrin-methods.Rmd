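---
title: "Methods: dehydrin segment detection, mining and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dehydrin segment detection, mining and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehydrin)
```

This vignette is the package's account of its models and numerical
choices: what each stage computes, which parameters matter and why their
defaults were chosen, what the synthetic-data generators do and do not
emulate, and where the design was genuinely open.

## Conserved-segment model

Dehydrins are intrinsically disordered, so their conserved features are
short linear segments rather than folded domains. The package models each
segment class with the simplest match model that captures it:

* **Scored windows** (`F_expanded`, `F_core`, `K`, `Y`). An ungapped
  window the length of the consensus slides over the protein; the window
  score is the sum of BLOSUM62 substitution scores against the consensus,
  and a window is a candidate when its score reaches a fraction *t* of
  the consensus self-score. Ungapped matching is appropriate because
  these segments are short (6–18 residues) and indels inside them are
  themselves evidence of a different family (see the mining filter
  below). Non-overlapping candidates are selected greedily by descending
  score with a leftmost tie-break, which makes copy counts deterministic.
* **Residue runs** (`S`). A serine tract is a maximal run of at least 4
  serines. Runs are a better model than windows here because the
  biological feature is the homopolymeric tract itself (a phosphorylation
  target), not a diverged consensus.
* **Windowed counts** (`H`). A histidine-rich segment is any region
  unionable from 9-residue windows containing at least 5 histidines. The
  rule is calibrated so that the canonical instance `HHQHHHHVE` (6 H in 9)
  is a clear positive while alternating or sparse histidines are not; the
  field reports instances rather than a rule, so the rule is the
  package's own and is fully configurable.

**Thresholds.** The default *t* = 0.6 for F- and K-segments is permissive
enough to accept diverged orthologs (about 6–7 average-cost substitutions
in an 18-mer) while random uniform backgrounds of length 100 produce a
false positive in fewer than 5% of sequences (measured in the test
suite). The Y-segment, being only 6 residues, uses *t* = 0.8; at 0.6 a
hexamer window would admit too much noise. Unknown residues (`X`) score 0
against everything: they neither support nor refute a match.

**Segment definitions.** The expanded F-segment consensus is
`ETKDRGLFDFLGKKEEEE` (18 aa; charged composition K₃E₅D₂R₁, net formal
charge −3) and the core F-segment is `DRGLFDFLGKK` (11 aa). The Y- and
K-segment consensuses are not standardized to a single string in the
literature; the package adopts `DEYGNP` for Y and the 15-mer
`EKKGIMDKIKEKLPG` for K. The K default was chosen specifically because
its charged composition is K₅E₂D₁, the composition reported for the
K-segment consensus in comparative charge analyses, which makes the
F-vs-K charge contrast (−3 vs +2) reproducible from the defaults. All
definitions are ordinary `motif_definition()` objects and can be
overridden.

## Architecture typing

Counts of Y, S, K and F segments convert to the YSK shorthand: `Y<n>`,
then `S` (with an explicit count when a protein carries more than one
tract, as in F₂S₂K<sub>n</sub> dehydrins), then `K<n>`; `+F<n>` is
appended when expanded F-segments are present, and the F-alias
(`F3SK2`-style) replaces the Y block with the F block. Subscript 1 is
written explicitly (`Y1K1`, `K1`) so the strings match the printed
conventions of family tables. Core-F hits nested inside an expanded-F
hit are the same segment and are counted once.

The type label is one of the five structural types. A protein without a
K-segment is `none` — the K-segment is the defining feature, so nothing
else can make a sequence a dehydrin. `KnS` versus `SKn` cannot be decided
from counts alone; the package uses segment order along the sequence and
assigns `KnS` only when every serine tract lies after the last K-segment.
This positional rule is an inference from the nomenclature (no published
instance was available to calibrate against) and is stated as such.

## Segment mining

Database mining re-expresses a two-round homology search as explicit
local alignment: Smith–Waterman with affine gaps (BLAST protein defaults,
open 11 / extend 1) of the consensus against every database protein.
Design choices:

* **Self-score fraction, not e-value.** An e-value gate depends on the
  database size and composition and cannot be reproduced across database
  versions. The package thresholds on score ≥ 0.5 × self-score, a
  query-intrinsic criterion. At 0.5 an 18-mer tolerates roughly 7
  average-cost substitutions, which comfortably covers ortholog
  divergence while random backgrounds essentially never reach it.
* **Iterative masked extraction.** Multiple copies per protein are found
  by repeatedly aligning and masking previous hits with `X` (score 0). A
  candidate alignment that overlaps a masked region (possible only by
  gapping across it) is rejected and extraction stops for that protein,
  which preserves the invariant that retained hits never overlap.
* **Duplicate handling.** Databases contain redundant entries; exact
  residue-string duplicates are dropped before mining and counted, so
  mining-then-merging and deduplicating-then-mining agree.
* **Gap filter.** Segments whose optimal alignment to the consensus
  contains an internal indel are removed by `filter_gapped_segments()`.
  The motivating instances are two-residue insertions splitting the
  consensus — a hallmark of a related but distinct family — and the
  filter generalizes them to any internal gap.

## Consensus, information content, and clustering

Equal-length mined segments tabulate into an L×20 positional count
matrix; the consensus takes the modal residue per position with
lexicographic tie-breaks (determinism; ties essentially never occur at
realistic sample sizes). Information content is log₂20 − H per position,
without small-sample correction by default because the package reports
raw counts, not corrected logo heights (a corrected mode is available).

The package ships `f_segment_profile()`, an 18-position modal-count
profile of the expanded F-segment across 208 mined orthologs (modal
counts E197, T67, K92, D188, R207, G207, L150, F200, D198, F204, L123,
G167, K142, K149, E93, E114, E105). The available tabulation lists 17
counts for the 18-residue consensus — the four terminal glutamates carry
only three counts — so the package assigns those counts to positions
15–17 and repeats the last value (105) at position 18. Any choice above
the uniform residual (about 6 per residue) leaves the consensus and its
recovery behavior unchanged; only the information content of that single
position is affected. The residual mass at each position is spread
uniformly over the other 19 residues, a maximum-entropy choice given that
only the modal counts are known.

Segment clustering uses neighbor joining on p-distances (mismatch
fractions; appropriate for equal-length ungapped segments). The NJ
implementation is the standard agglomerative algorithm with two
determinism guarantees: Q-matrix ties resolve to the smallest index pair,
and negative branch lengths (which arise on non-additive input) are
clamped to zero with the deficit moved to the sister branch so the joined
pair's path length is preserved. On additive distances the algorithm
recovers the generating tree exactly (verified against an independent
implementation in the test suite). Class assignment cuts an
average-linkage hierarchical clustering of the same distances into *k*
groups (default 5, matching the number of classes conventionally drawn
for the mined F-segment set). Whether the original tree software used NJ
or another agglomerative method is unknown, so exact class memberships of
any particular published figure are not a target; the package's claim is
only that its own tree and classes are deterministic, correct on additive
input, and reasonable on p-distances.

## Biophysics

Net formal charge counts K and R as +1 and D and E as −1, with histidine
and the termini neutral. This segment-level convention is the only one
under which the expanded F-segment's composition (K₃E₅D₂R₁) gives the
reported net charge of −3; it is deliberately simpler than a pH-dependent
model, being a composition summary rather than a titration.

The isoelectric point, by contrast, is a whole-protein titration
statistic: bisection on the Henderson–Hasselbalch net charge over side
chains (D, E, C, Y, H, K, R) and both termini, to |charge| < 10⁻³ or a pH
step below 0.002, reported to 2 decimals. The default pKa set is
Bjellqvist (Expasy-compatible); EMBOSS is selectable because the tool
originally used for such tables is unspecified and the two sets bracket
common practice. Molecular weight sums average residue masses plus one
water; `X` is rejected there because its mass is undefined.

Hydropathy uses the standard Kyte–Doolittle index with a centered moving
average; the default window is 1 (raw indices) because the segments of
interest are 11–18 residues long and a 9- or 19-residue smoothing window
— standard for whole proteins — would erase exactly the structure being
inspected. Edges truncate the window to available residues rather than
padding. GRAVY is the unweighted mean of raw indices, so
`gravy == mean(values)` holds identically at window 1.

## Expression analysis

The comparative-Ct pipeline follows the standard three-step arithmetic:
ΔCt = Ct(test) − Ct(reference) with replicates averaged per (sample,
gene); ΔΔCt = ΔCt(sample) − ΔCt(baseline); fold = 2^−ΔΔCt with the
baseline month defined as 1. Significance against the baseline uses a
two-tailed Student's t-test (equal-variance by default, matching the
classical test; Welch by flag) on per-replicate fold values, with
technical replicates of the independent experiments pooled. How the
original design pooled its "triplicate × two experiments" structure is
not stated anywhere authoritative, so the package states its pooling
openly and keeps it configurable; with 3 × 2 = 6 replicate folds per
sample the test has ample power for the 6–15-fold seasonal changes of
interest (≥ 90% power for `**` at January-vs-August fold 15 and Ct noise
0.2 cycles, measured by simulation in the acceptance script). Zero
variance (noise-free simulations) yields `p = NA` rather than an error.

Amplification efficiency is the textbook dilution-curve statistic: the
least-squares slope of Ct against log₁₀(dilution) gives
E = 10^(−1/slope) − 1, so a perfect doubling series (slope −3.3219)
yields E = 1 exactly. In-silico PCR requires exact primer matches
(forward on the given strand, reverse complement downstream) because the
primers this models were designed against the very sequences being
checked; mismatch-tolerant binding would only add false products.

## Synthetic data: what it does and does not emulate

The generators define the package's test conditions:

* `simulate_dehydrin()` plants exact motif templates in spec order with
  random linkers of 8–20 residues drawn from a hydrophilic pool
  (G, T, E, K, P, A), then applies i.i.d. substitutions. Serine is
  excluded from the linker pool so that linkers cannot form spurious
  S-tracts; with S included, a ~4-residue serine run would arise by
  chance in roughly 1% of linkers and break architecture round-trips at
  mutation rate 0 for reasons unrelated to the classifier. F copies are
  placed N-terminally, mirroring multi-F dehydrins.
* `simulate_segment_db()` plants 0–3 expanded F-segment copies per
  protein (default mix 10/50/25/15%) with 15–40-residue linkers.
* `sample_from_frequency_profile()` samples segments independently per
  position — a columnwise exchangeable model with no covariation between
  positions.
* `simulate_ct_table()` writes Ct(test) = Ct₀ − log₂(fold) + N(0, σ) and
  Ct(ref) = Ct₀ + N(0, σ) with σ = 0.2 cycles by default, 3 technical
  replicates × 2 experiments over the August–February seasonal design
  with default trajectory 1, 1, 2, 5, 12, 9 (folds within the 6–15×
  range typical of cold-acclimation responses).

What passing these tests shows: the scanner, miner, classifier, consensus
and ΔΔCt machinery invert their own generative models exactly or within
stated tolerance. What it does not show: real proteomes have compositional
bias, repeats and partial segments that uniform linkers do not model;
real logos have inter-position covariation; real qPCR noise is not
homoscedastic Gaussian and efficiencies are not exactly 2. The
accession-dependent facts (three F-copies in a 303-residue multi-F
dehydrin, two in its crucifer ortholog, a 254 bp reference-gene amplicon)
require downloading the corresponding GenBank records and are documented
manual checks, not test fixtures.

## Problem sizes and determinism

Every generator takes an explicit integer seed and is bit-reproducible.
The shipped test and acceptance runs use desk-scale sizes — 20–40-protein
databases, 208-segment samples with 100 replicates, 4–8-taxon trees,
100-simulation power estimates, 200 alignment-oracle pairs — chosen so
the whole suite completes in well under a minute while keeping the
Monte-Carlo standard errors far from the decision boundaries (e.g. the
observed mean fold-recovery error is ~9% against a 25% bound, and
consensus recovery is 100/100 against a 95% bound).

## Known limitations

* Ungapped window scanning cannot call a segment split by an internal
  indel; such cases surface in mining (as gapped hits) but not in
  per-protein scans.
* The KnS/SKn positional rule is an inference from nomenclature, as no
  calibrating instance exists.
* The pI depends on the pKa set (Bjellqvist and EMBOSS differ by up to
  ~0.3 pH units on acidic proteins); report which set you used.
* Copy counting attributes overlapping candidate windows to the single
  best placement; tandem segments closer than one motif length are
  merged into one call.
* The e-value semantics of the original database searches are
  intentionally not reproduced; hit counts against live databases are
  database-version-dependent and out of scope.
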