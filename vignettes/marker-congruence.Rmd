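---
title: "Evaluating phylogenomic marker sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating phylogenomic marker sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomarkers)
```

## The problem

Concatenated ("supermatrix") phylogenomics of deep archaeal lineages is
sensitive to the marker genes chosen: individual markers can carry
horizontally transferred copies or contaminant sequences whose gene trees
disagree with the species history, and a handful of such markers can pull a
deep-branching focal clade — one that different studies place either with a
TACK-like neighborhood or with an Asgard-like one — from one side of the
tree to the other. This package implements the evaluation loop used to make
that choice auditable: pool published marker sets, rank each marker by the
congruence of its own gene tree with well-established lineages, build
occupancy-filtered supermatrices from the top-ranked markers, classify each
marker's placement tendency for the focal clade, and profile
eukaryotic-signature-protein (ESP) repertoires across genomes.

## Congruence ranking

A lineage definition is a named genome set. On an unrooted gene tree the
lineage, restricted to its members present as leaves, is **monophyletic**
iff some edge induces a bipartition whose one side is exactly the present
members. Lineages with fewer than `min_present = 2` present members are
**not evaluable**: a singleton is vacuously monophyletic, and counting it as
a success would reward sparse markers. The marker's score is the fraction of
evaluable lineages recovered, in [0, 1]; markers with no evaluable lineage
have an undefined score and are dropped from the ranking.

This simple fraction is deliberately the whole statistic. Published ranking
procedures in this area derive from earlier pipelines whose exact weighting
(by branch support, by split depth) is not restated alongside the set sizes
they report; rather than guess, the score here is the auditable core, and
the per-clade verdicts are retained on every `congruence_score` so weighted
variants can be layered on without re-walking the trees.

Ranking sorts by score (descending), then number of evaluable clades
(descending — a 9/9 marker outranks a 2/2 marker), then marker id, so output
order never depends on input order. The selection size is
`round(fraction * n)` (half away from zero), with an explicit `k_override`
because published set sizes need not equal the exact fraction of the pool.

## Placement tendency and Venn overlap

Per marker tree, the tree is rooted on its outgroup leaves when they are
present *and* form a clade of the unrooted tree (the precondition of
outgroup rooting); otherwise by midpoint. Midpoint is the fallback rather
than an error because contaminant events can legitimately break outgroup
monophyly in a gene tree. If fewer than two focal genomes are present, or
the focal clade is not monophyletic on the rooted tree, the marker is
`UNRESOLVED` — a broken focal clade is never majority-voted into a
placement, which keeps every label traceable to a single sister subtree.
Otherwise the focal clade's sister leaves are tallied by group (A-series
versus B-series clade names; outgroup leaves ignored), and the marker is
labelled `WITH_A` or `WITH_B` when the corresponding fraction strictly
exceeds `majority` (default 0.5, so an exactly even sister is
`UNRESOLVED`).

"Tendency toward a neighborhood" could also be operationalized as
nested-within or any-non-A placement; the sister-composition rule was chosen
because it is symmetric in A and B, decided by one subtree, and recovers
forced grafts exactly in simulation (a property the test suite asserts at
200 markers).

`venn_overlap()` assigns every marker in the union of 2–4 named sets to
exactly one region — its exact membership signature — and reports each
region's `WITH_B` percentage to one decimal place with half-up rounding,
matching the precision such percentages are conventionally reported at.

## Supermatrices

A column is *present* in a taxon iff its residue is neither `-` nor `?`;
`X` counts as present because it is a residue of unknown identity, not
missing data (this reading of the occupancy rule is configurable in
principle and documented here because published methods rarely state it).
Genomes lacking a marker receive all-gap rows before filtering, so they
count as absent. A column is kept iff present in at least
`ceiling(threshold * n_taxa)` taxa, `threshold = 0.6` by default — the
conventional 60% occupancy rule. Partition intervals are stored 0-based
half-open internally and written 1-based inclusive, the dialect common
phylogenetics partition files use; the on-disk dialect is a package
decision, not a community standard.

Down-sampling over-represented clades uses a greedy
maximum-sum-of-pairwise-path-distances heuristic on a guide tree: farthest
pair first, then repeatedly the genome adding the most summed distance,
ties broken alphabetically. Focal and outgroup genomes bypass quotas —
they are the taxa the analysis is about and the taxa that root it.

## ESP profiles and UPGMA

Presence-absence profiles are compared with the Jaccard distance by default
(1 − |∩|/|∪| of the family sets, defined as 0 for two all-zero profiles),
which is robust to repertoire-size differences; Hamming is available. No
published metric is claimed — the choice is configurable and the dendrogram
is not asserted to reproduce any specific published figure.

UPGMA is implemented directly rather than through a generic clustering
routine because its determinism contract matters here: ties are broken by
the smallest (row, column) index pair in the current cluster order, and
merge heights are *half* the merge distance so the cophenetic distance
between two leaves equals the linkage value at which they joined. The test
suite cross-checks cophenetic matrices against an independent
average-linkage implementation on random 6×6 matrices and asserts
ultrametricity to 1e-9.

## The synthetic generator

`sim_config()` defines the simulated study: a rooted species tree
`(outgroup, (A-series, (focal, B-series)))` with uniform branch lengths on
[0.05, 0.3]; per-marker gene trees copied from it with multiplicative
lognormal branch jitter (`sigma = 0.2`); with probability `hgt_rate` the
focal clade is pruned and regrafted onto a random edge inside the target
series; with probability `contaminant_rate` one non-focal leaf is moved
into a different series. Grafts and moves preserve leaf counts so taxon
sets stay comparable across markers. Alignments evolve under WAG with equal
site rates — enough signal for recovery tests without the
site-heterogeneous mixtures real analyses use. Every event lands in a truth
table, and identical config plus seed reproduces every output byte for
byte.

Defaults are fixed once: 4 A-clades, 4 B-clades, 4 taxa per clade, 4
outgroup and 4 focal genomes (40 taxa — large enough that clade monophyly
is non-trivial, small enough that a 200-marker simulation runs in seconds),
`hgt_rate = 0.2`, `contaminant_rate = 0.05` — minority discordance, the
regime in which ranking is useful at all.

What the generator does *not* emulate: incomplete lineage sorting (grafts
are the only topological discordance), indels and alignment error (gaps
arise only from whole-missing taxa), rate heterogeneity across sites and
lineages, and compositional biases that drive long-branch attraction.
Passing recovery tests therefore shows the classifiers are correct on
transfer-like discordance with adequate signal, not that they are robust to
every artifact real single-gene trees carry.

## Numerical and degenerate-input choices

- Dual branch supports parse from `"UFBoot/SH-aLRT"` labels; an absent
  component is `NA`, never 0, because 0 is a meaningful support value.
- Unrooted trees may carry a trifurcating root node; rooting is always an
  explicit operation.
- Zero-length branches are legal everywhere (a star tree evolves identical
  sequences); negative lengths are a parse error.
- Marker accessions are case-folded and version-stripped before comparison;
  "nonredundant" is defined as normalized-accession identity plus an
  explicit, auditable alias table, alias chains capped at depth 10.
- Markers whose trees lack every lineage are excluded from ranking rather
  than scored 0, so absence of evidence does not rank below contrary
  evidence.

## Problem sizes used by the tests

The suite runs monophyly against exhaustive edge-deletion enumeration on
random trees of 4–8 leaves over all leaf subsets; tendency recovery and
clean-versus-grafted ranking at 200 markers on 40 taxa; alignment
divergence at 50 Monte-Carlo replicates; UPGMA cross-checks on 6×6
matrices; and the pipeline end-to-end at 12 markers with 40-column
alignments. These sizes make the full suite run in well under a minute
while leaving each property's failure modes reachable.

## Limitations

Maximum-likelihood inference itself (site-heterogeneous mixtures, UFBoot /
SH-aLRT computation), homology search, and genome annotation are out of
scope: the package prepares inputs for and parses outputs of external tree
programs. Tendency labels summarize one sister relationship per marker; they
are not a topology test and carry no support-value weighting. The catalog
fixture shipped under `inst/extdata/` is synthetic (see its README): it
reproduces the structure of a published marker catalog — set sizes,
provenance counts, intersection sizes — not its accessions.
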