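# Independent oracles used across tests.

# Splits of an unrooted tree computed by edge deletion on an igraph graph:
# for every edge, the tip set of the component containing the edge's child.
# Independent of the package's postorder accumulation.
igraph_splits <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  ntip <- ape::Ntip(tree)
  lapply(seq_len(nrow(tree$edge)), function(k) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, as.character(tree$edge[k, ])))
    comp <- igraph::components(g2)$membership
    side <- names(comp)[comp == comp[[as.character(tree$edge[k, 2])]]]
    leaf <- as.integer(side[as.integer(side) <= ntip])
    sort(tree$tip.label[leaf])
  })
}

# Brute-force monophyly verdict from enumerated splits (pass precomputed
# splits when testing many subsets of one tree).
oracle_monophyly <- function(tree, members, min_present = 2L,
                             splits = igraph_splits(tree)) {
  present <- sort(intersect(members, tree$tip.label))
  if (length(present) < min_present) return("not_evaluable")
  if (length(present) == ape::Ntip(tree)) return("monophyletic")
  all_tips <- sort(tree$tip.label)
  for (s in splits) {
    if (identical(s, present) || identical(sort(setdiff(all_tips, s)), present))
      return("monophyletic")
  }
  "violated"
}

# Canonical set-of-splits representation for topology comparison: each split
# keyed by its lexicographically smaller side.
split_key_set <- function(tree) {
  tips <- sort(tree$tip.label)
  keys <- vapply(tree_bipartitions(tree), function(s) {
    s <- sort(s); o <- sort(setdiff(tips, s))
    a <- paste(s, collapse = "|"); b <- paste(o, collapse = "|")
    if (a < b) a else b
  }, character(1L))
  sort(unique(keys))
}

same_topology <- function(t1, t2) {
  setequal(t1$tip.label, t2$tip.label) &&
    identical(split_key_set(t1), split_key_set(t2))
}

# Small random alignment matrix with gaps.
random_alignment <- function(taxa, ncol, gap_prob = 0.3) {
  res <- sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-"),
                length(taxa) * ncol, replace = TRUE,
                prob = c(rep((1 - gap_prob) / 20, 20), gap_prob))
  matrix(res, nrow = length(taxa), dimnames = list(taxa, NULL))
}

# Taxonomy + newick for the minimal worked tendency examples.
toy_taxonomy <- function() {
  data.frame(
    genome_id = c("out", "f1", "f2", "k1", "k2", "as1", "as2"),
    clade = c("Out", "Focal", "Focal", "Kor", "Kor", "Asg", "Asg"),
    role = c("outgroup", "focal", "focal", "ingroup", "ingroup",
             "ingroup", "ingroup"))
}
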