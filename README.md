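# phylomarkers

Tools for evaluating phylogenomic marker-gene sets in deep archaeal
phylogeny — for researchers who need to know *which* conserved single-copy
proteins to concatenate when the placement of a deep-branching lineage
(here: a focal clade that wanders between a TACK-like and an Asgard-like
neighborhood) depends on the marker set chosen.

## What it does

- **Pooling.** Merge published marker catalogs into one nonredundant catalog
  with per-source provenance (`dereplicate()`), via accession normalization
  and an explicit alias table.
- **Congruence ranking.** Score every marker's single-gene tree by the
  fraction of well-established lineages it recovers as monophyletic, and
  select top-fraction sets (`is_monophyletic()`, `score_markers()`,
  `rank_and_select()`). On an unrooted gene tree *T* with lineage *L*
  restricted to its present members *L'*, *L* is monophyletic iff some edge
  of *T* induces the bipartition {*L'*, leaves ∖ *L'*}; the score of a
  marker is

  `score = n_monophyletic / n_evaluable`

  over all lineages with ≥ 2 members present.
- **Supermatrices.** Concatenate per-marker alignments keeping only columns
  present (non-gap, non-`?`) in ≥ ⌈*t*·*n*⌉ of *n* taxa (default *t* = 0.6),
  with partition files and occupancy bookkeeping (`concatenate()`,
  `write_partitions()`), plus diversity-greedy down-sampling of
  over-represented clades (`downsample()`).
- **Placement tendency.** For each marker tree, root (outgroup, else
  midpoint), find the focal clade's sister, and label the marker `WITH_A` /
  `WITH_B` / `UNRESOLVED` by strict-majority sister composition
  (`classify_tendency()`); summarize multi-set overlaps with per-region
  `WITH_B` percentages (`venn_overlap()`).
- **Signature-protein profiles.** Presence-absence matrices from hit tables,
  Jaccard/Hamming distances, and UPGMA dendrograms with deterministic
  tie-breaks (`build_matrix()`, `profile_distance()`, `upgma()`).
- **Synthetic ground truth.** A generator for species trees, gene trees with
  controlled horizontal-transfer grafts and contaminant leaves, alignments
  evolved under WAG, and signature-protein hit tables (`sim_config()`,
  `simulate_dataset()`), so every downstream stage is testable without
  genome downloads.
- **Pipeline.** `run_pipeline()` orchestrates all stages with a manifest,
  byte-identical reruns under a fixed seed, and `--resume` support; a thin
  CLI lives at `inst/cli/phylomarkers.R`.

## Worked example

Simulate 40 marker trees over a 40-genome species tree in which 40% of
markers carry a focal-clade graft, rank them, and compare selections:

```r
library(phylomarkers)
cfg <- sim_config(n_markers = 40, hgt_rate = 0.4, contaminant_rate = 0,
                  graft_target = "random", seed = 11)
sp  <- simulate_species_tree(cfg)
gt  <- simulate_gene_trees(sp$tree, sp$taxonomy, cfg)
clades <- clades_from_taxonomy(sp$taxonomy, roles = c("ingroup", "outgroup"))
scores <- score_markers(gt$trees, clades)
head(scores[, 1:4])
#>   marker_id n_evaluable n_monophyletic     score
#> 1      m001           9              9 1.0000000
#> 2      m002           9              9 1.0000000
#> 3      m003           9              9 1.0000000
#> 4      m004           9              9 1.0000000
#> 5      m005           9              9 1.0000000
#> 6      m006           9              8 0.8888889
```

`m006` breaks one of nine evaluable lineages, so its score is 8/9. Ranking
and tendency classification:

```r
sel25 <- rank_and_select(scores, 0.25)
sel50 <- rank_and_select(scores, 0.50)
ga <- grep("^A", unique(sp$taxonomy$clade), value = TRUE)
gb <- grep("^B", unique(sp$taxonomy$clade), value = TRUE)
tend <- classify_tendencies(gt$trees, sp$taxonomy, ga, gb)
table(tend$label)
#> WITH_A WITH_B
#>      5     35
venn_overlap(list(top25 = sel25$selected, top50 = sel50$selected), tend)[, 1:4]
#>        region  n n_with_B pct_with_B
#> 1 top25&top50 10        9         90
#> 2       top50 10       10        100
```

The focal clade sits sister to the B series in the species tree, so clean
markers are `WITH_B`; the five `WITH_A` labels are exactly the grafts into
the A series (checkable against `gt$truth`). Each Venn region reports how
many of its markers place the focal clade with the Asgard-like series and
the percentage to one decimal.

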