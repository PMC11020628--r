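# ltrscout

Signature-based detection of LTR retrotransposons in genome assemblies —
including solo LTRs, sequential same-family runs, and recently nested
insertions down to multiple nesting levels — for researchers annotating
repeat-rich (typically plant) genomes without a curated repeat library.

## The method in brief

An LTR retrotransposon is `5'LTR — internal part (with a polypurine
tract) — 3'LTR`, flanked by a ≥ 4 bp target-site duplication. `ltrscout`
finds this signature directly:

1. **Scorer** — every 13-mer is scored by the distance to its nearest
   identical copy downstream (forward track) and upstream (backward
   track), within [400, 27000] bp; the two directions are independent,
   which keeps score runs over the LTRs of nearby same-family elements
   unfragmented (the "castle problem").
2. **Merger** — runs of equal scores become stretches (height = median of
   non-zero scores); stretches merge when heights differ by less than the
   similarity margin `round(16.30 + 3·19.62) = 75` bp across gaps < 75 bp,
   via a seven-step statistical procedure.
3. **Detector** — a linear classifier (SGD) over 10 features (sizes, gap,
   height difference, repeat-content statistics, same-repetitive-region
   flag) finishes assembling stretches into candidate LTRs; candidates
   < 200 bp are discarded. Repeat content comes from a genome-trained
   k-mer fold-over-expectation profile.
4. **Matcher** — candidates become nodes of a directed-weighted graph
   (edge weight = shared k-mer fraction, threshold 0.27; internal parts
   must be ≥ 0.33 repetitive); connected components resolve into single
   elements, element + solo LTR, recently nested pairs (inner/outer
   internal identity > 60%), and complex regions (≥ 2 inter-node regions
   at ≥ 80% identity). Deep nests are peeled recursively by splicing
   resolved inner elements out and re-running the pipeline.
5. **Filter & post-process** — length bounds ([200, 7000) bp LTRs, ≥ 200
   bp internal), LTR similarity (length ratio ≥ 0.8 or Smith–Waterman
   rescue), polypurine tract (poly-A probe vs the G→A-converted window
   upstream of the 3' LTR, with a reversed-orientation fallback), a MITE
   veto (both LTRs showing terminal inverted repeats), orphan-solo
   removal, and TSD annotation by longest common substring of the 20 bp
   flanks.

A synthetic plant-genome simulator with exact truth annotations, the
semi-synthetic training-genome construction, and a reciprocal-overlap
evaluation harness are part of the package, so every stage is testable
offline.

## Worked example

```r
library(ltrscout)

# a 300 kb synthetic genome: two families, one solo LTR, one nested insertion
ts <- generate_genome(
  list(plant_spec("copia1", copy_number = 3, solo_count = 1),
       plant_spec("gypsy1", ltr_length = 400, internal_length = 2500,
                  copy_number = 3,
                  nesting = plant_spec("gypsy1", ltr_length = 400,
                                       internal_length = 2500,
                                       ltr_divergence = 0.01))),
  3e5, seed = 42)
ts
#> truth_set: 322740 bp genome, 7 elements, 1 solo LTRs, 0 decoys

anns <- detect_ltrs(ts$genome)
annotations_to_df(anns)[, c("start", "end", "kind", "nesting_level")]
#>    start    end     kind nesting_level
#> 1 108618 111919  element             1
#> 2   2174   5180  element             0
#> 3  35947  38947  element             0
#> 4  69152  72173  element             0
#> 5 106815 113420  element             0
#> 6 144687 147987  element             0
#> 7 183818 187114  element             0
#> 8  74745  75118 solo_ltr             0

evaluate_predictions(anns, ts$annotations)$metrics
#>    recall precision        f1
#>         1         1         1
```

Row 1 is the nested `gypsy1` copy (nesting level 1) correctly resolved
inside the element spanning 106815–113420; every element also carries a
polypurine-tract interval and target-site duplications (columns
`ppt_start`/`ppt_end`, `tsd5_*`/`tsd3_*`). Coordinates are 0-based
half-open; `write_annotations()` emits BED (0-based) or GFF3 (1-based)
with PPT/TSD child features.

A command-line interface covers the same workflow:

```sh
Rscript -e 'ltrscout::ltrscout_cli()' simulate --length 500000 --seed 7 --out sim
Rscript -e 'ltrscout::ltrscout_cli()' detect sim.fa --out results --bed --gff
Rscript -e 'ltrscout::ltrscout_cli()' eval --pred results/ltrscout.bed --truth sim.bed
```

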