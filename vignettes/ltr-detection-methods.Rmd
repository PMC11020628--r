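---
title: "Signature-based LTR retrotransposon detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based LTR retrotransposon detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An LTR retrotransposon is bounded by two near-identical long terminal
repeats (LTRs, here 200-7000 bp each) in the same orientation, flanking an
internal part that carries a polypurine tract (PPT) just upstream of the 3'
LTR. Insertion leaves a short (>= 4 bp) target-site duplication (TSD) on
both flanks. `ltrscout` annotates such elements in genome assemblies from
this structural signature alone -- no repeat library, no protein-domain
scan -- which is what lets it find non-autonomous elements and recently
nested (same-family element-within-element) insertions.

# The detection model, stage by stage

## Match-distance scoring

Every k-mer (k = 13 by default) is matched to its nearest identical copy
downstream (forward track) and, independently, upstream (backward track),
provided the distance between start positions lies in [400, 27000] bp --
the plausible range of LTR-to-LTR distances. The score is that distance,
else 0. Two independent directional tracks avoid the *castle problem*:
with a single "nearest match either way" track, nearby same-family
elements steal each other's nearest matches and the score runs over the
LTRs fragment into alternating-direction shards. With two tracks, the 5'
LTR of the left element points cleanly at its own 3' LTR in the forward
track, whatever its neighbours do.

## Merging scores into stretches

Runs of the same exact non-zero score become *stretches* (height = median
of the non-zero scores, size = run length). Stretches of size >= 16 bp are
`keep`, smaller ones `delete`. Mutations between two LTRs appear as short
zero-score gaps; modelling the within-LTR gap sizes as normal with mean
16.30 bp and sd 19.62 bp gives a similarity margin of
`round(16.30 + 3 * 19.62) = 75` bp (three standard deviations cover 99.7%
of the distribution). The seven-step procedure then (1) groups, (2)
labels, (3) merges adjacent stretches whose heights differ by < 75 across
gaps < 75, (4) removes *interruptive* delete-stretches sitting between two
stretches that would merge without them, (5) re-merges, (6) removes the
remaining delete stretches, and (7) re-merges. Each merge stage runs a
left-to-right scan to a fixpoint, which makes the result scan-order
independent; `merge(merge(x)) == merge(x)` is asserted in the test suite.
A merged stretch's height is recomputed as the median over the pooled
member runs -- not an average of heights -- because height is defined as a
median of scores.

## Assembling candidate LTRs (the detector)

Merging by score statistics alone ignores context: an old element's
fragmented stretches should still fuse if they sit in the same repetitive
region. A linear classifier (stochastic gradient descent; logistic or
hinge loss) decides for each consecutive stretch pair whether to merge,
from 10 features: the two sizes, the gap, |delta height|, |delta median
non-zero repeat score|, |delta mean repeat score|, the mean repeat scores
of the two stretches and the gap, and a binary same-repetitive-region
flag. Features 1-9 are standardized with training-set statistics; the
binary flag is left alone. Training follows a 70/20/10 split with a
random-search 10-fold cross-validation over hyperparameters (iteration
count configurable; the packaged model used 60 draws), keeps the best
validation-F1 candidate, reports held-out test metrics, then refits on
the full data. Accepted pairs chain transitively; candidates shorter than
200 bp (the minimum LTR size) are discarded.

The packaged model (`inst/extdata/merge_model.json`, regenerated by
`tools/train_default_model.R`) was trained on semi-synthetic genomes:
several families at 6-15% divergence with a low indel rate -- indels are
what actually fragment stretches, because substitutions alone do not
change match distances -- plus low-divergence solo and sequential layouts
that contribute the crucial "do not merge across a whole internal part"
negatives.

## Repeat-content profile

A stand-in for a genome-wide repeat scorer, honoring the published output
contract rather than any tool's internals: count every k-mer over the
whole genome set, compute its expected count under an order-2 Markov
background fitted to the same sequences, and score each k-mer start
`max(0, observed / max(1, expected) - 1)`. The floor of one on the
expectation encodes "a k-mer seen once is never repetitive"; without it,
any duplicated k-mer in a small genome would count as a repeat. The
profile k defaults to `max(13, ceil(log4(genome length)) + 2)` so the
chance expectation of a specific k-mer stays well below one. Repetitive
regions are maximal positive runs with gaps <= 50 bp closed and runs
< 100 bp dropped. Cross-species mode simply pools the counts over all
genomes in the set while scoring each sequence separately, so shared
families gain support from every species.

## Matching LTRs in a directed-weighted graph

Forward and backward candidates become nodes. A node points where its
stretches' heights indicate: for each member stretch, the interval
[start + height, end + height) (mirrored for backward nodes) -- not every
individual scored position, which would scatter spurious edges from
mutated positions. An edge is added to each opposite-direction node that
interval hits; its weight is the fraction of the source's k-mers with an
exact copy in the target. Overlapping forward/backward nodes are joined by
unweighted *vertical connections* (they are the same physical LTR), and
connected components are taken over both edge kinds.

*Hyper-extension* (a candidate wrongly fused with a neighbouring
unrelated repeat) shows up as strongly asymmetric mutual weights. Each
node is judged only against its best mutual partner (highest return
weight); if its outgoing weight is below half the return weight, the node
is trimmed to the sub-interval whose k-mers actually match that partner
and all touching weights are recomputed. Judging against the best partner
matters: in nested same-family regions a node has many weak mutual
partners, and trimming against an arbitrary one destroys true LTRs.

Components resolve case by case:

* **single** -- a forward node and a downstream backward node pointing at
  each other with both weights >= 0.27 and an internal part whose
  repetitiveness ratio is >= 0.33. All qualifying pairs are kept;
  overlapping survivors are all reported and left to the filters.
* **solo** -- three chained LTR loci; the spacer repetitiveness decides
  which pair is the element and which locus the solo LTR. If both
  in-between regions are repetitive, all three pairings are emitted.
* **recently nested** -- an inner single pair flanked by an outer forward
  node upstream and backward node downstream that point into it. The
  windows immediately flanking the inner element belong to the outer
  internal part; they must be repetitive and share > 60% identity (the
  "recent" operating range) with the inner internal part. Local alignment
  is used for this confirmation because the outer internal is fragmentary
  at this stage -- a global alignment of mismatched-length pieces is
  uninformative. Among qualifying inner pairs the one with the highest
  mutual weight is claimed: a *recently* nested insertion has
  near-identical LTRs, so the true inner pair outranks same-family
  cross-pairings.
* **complex** -- no qualifying pair, >= 4 loci: inter-node regions are
  compared all-vs-all and a complex region is reported if two of them
  reach 80% identity (sequential same-family insertions).
* **deeply nested** -- handled by the pipeline: the inner element of a
  recently nested pair is recorded, spliced out of the sequence, and the
  scorer-through-matcher stages re-run on the spliced sequence (the
  repeat profile is reused through a coordinate map, not retrained). One
  inner element is peeled per component per round, up to depth 5. Outer
  elements are deliberately *not* emitted from the approximate nested
  geometry; they surface as clean singles in a later round, which gives
  much better boundaries. Coordinates are lifted back through the splice
  map; nesting levels are assigned by containment at the end.

## Boundary extension, filters, post-processing

The 3' LTR is extended by k-1 bp (the last score belongs to the last
k-mer, not the last nucleotide). If the paired LTRs differ in length, the
shorter is tentatively extended backward and forward by the missing
length; an extension is kept only if the global LTR-pair identity strictly
improves *and* the added snippet resembles (> 50% identity) the
corresponding terminus of the longer LTR. The snippet guard is needed
because under the matches/alignment-length metric an extension into random
background always nudges identity up slightly.

Filters (conjunctive; an element must pass all): LTR lengths in
[200, 7000), internal >= 200 bp with nested child spans excluded (as a
union, so grandchildren are not double-counted); LTR length-coverage
ratio >= 0.8 or a local-alignment rescue (>= 80 bp, >= 80% identity); a
PPT found by aligning a 100 bp poly-A probe against the G-to-A-converted
last 400 bp of the internal part (alignment > 12 bp and more A than G in
the matched region), with a reversed-orientation T/C fallback on the
first 400 bp after the 5' LTR; and a MITE veto that drops an element only
when *both* LTRs show terminal inverted repeats (first 30 bp vs the
reverse complement of the last 30 bp, > 15 bp aligned at > 85%
identity). Solo LTRs survive only if their component kept at least one
element. Finally the 20 bp flanks are searched for the longest common
substring; a >= 4 bp hit is reported as the TSD (ties resolve to the
occurrences closest to the element) and the element is widened to touch
it.

Local alignments use match +2, mismatch -3, gap open -5, gap extend -2.
The scheme matters: with a lenient mismatch penalty, local alignments of
unrelated flanks drift far past the homologous core and dilute identity
below the 80%/85% thresholds these filters depend on.

# The synthetic world

`generate_genome()` builds an i.i.d. background at GC 0.42 (plant-like)
and plants families described by `plant_spec()`: consensus LTR + internal
with an embedded PPT (>= 13 bp, >= 80% purine, inside the last 400 bp),
copies drifting from the consensus at half the family divergence (so
`family_divergence` reads as pairwise divergence between copies), a 3'
LTR mutated from the 5' at `ltr_divergence`, TSDs copied from the
insertion site, solo LTRs placed 2-8 kb downstream of full copies,
sequential runs 1-3 kb apart, nests inserted mid-internal (clear of the
PPT) with their own TSDs, and MITE decoys (terminal inverted repeats, no
internal signature) clustered within the scorer window so they genuinely
tempt the matcher. Substitutions only by default; `indel_rate` adds
geometric indels (mean ~30 bp, capped at 150) and is used for classifier
training worlds. `make_semisynthetic()` implements the four-step
training-genome construction: extract truth elements, permute the
residues of every inter-element region, reinsert the elements at their
original positions; length, element bytes and per-region base multisets
are preserved exactly.

`benchmark_genome()` is the stated validation world: 1 Mb, 17 elements in
four families (5 + 5 + 4 + 3, including two one-level nests and one
two-level nest), 3 solo LTRs, 6 MITE decoys, everything at pairwise
divergence <= 0.05. Nested children use near-identical LTRs (0.005-0.01)
-- that is what "recently nested" means biologically, and it is also what
makes the inner pair identifiable at all; parents and ordinary copies use
0.015-0.05. Independent insertions sit >= 30 kb apart so unrelated
copies stay outside the match window.

What a green end-to-end test does establish: the signature logic --
scoring, merging, classification, graph matching, nest peeling, filters
-- recovers planted structure at realistic divergence with >= 90% recall
and precision. What it does not establish: performance on real genomes,
whose backgrounds contain tandem repeats, segmental duplications, old
degenerate elements and non-LTR repeat families that this neutral
background does not model, and whose LTR families are far older and more
heterogeneous than the planted ones.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at the GFF3 writer (and R's 1-based `substr` slicing).
* "Similar" heights and bridgeable gaps both use strict `< margin`.
* Ties in the TSD search resolve to the pair closest to the element
  boundaries, since TSDs abut the insertion site.
* The castle regression fixture uses identical LTRs within each element
  and 2% divergence between the two elements: the regression isolates the
  two-track property; at higher within-element divergence, runs of >= 16
  mutated positions legitimately produce separate keep-stretches that
  only the detector (not the merger) is meant to fuse.
* Training labels for the merge classifier derive from synthetic truth
  (both stretches >= 50% inside the same truth LTR); the original
  training corpus and its labeling rule are not reproducible.
* The evaluation harness counts a prediction as a true positive at 80%
  reciprocal overlap with one-to-one greedy matching (largest overlap
  first, leftmost on ties). Precision in the acceptance run is computed
  with unmatched predictions as false positives, which is *stricter* than
  the dataset-based false-positive definition used on real genomes (where
  the truth is incomplete and overlapping extra predictions are expected
  output).

# Known limitations

* Minus-strand elements are handled only through the reversed-orientation
  PPT hypothesis; the scorer itself is strand-symmetric but no
  reverse-complement pass is made.
* The complex case reports a region, not resolved elements, mirroring the
  method's own refusal to over-interpret sequential same-family runs.
* Recursion depth is capped at 5 nesting levels.
* The fast k-mer identity estimator is a convenience honoring a +/- 0.05
  contract inside the trusted ranges; the exact Needleman-Wunsch identity
  is the default everywhere.
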