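test_that("monophyly verdicts on hand-built quartets", {
  good <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  bad <- read_newick("((a1:1,b1:1):1,(a2:1,b2:1):1);")
  cl <- clade_definition("A", c("a1", "a2"))
  expect_equal(is_monophyletic(good, cl), "monophyletic")
  expect_equal(is_monophyletic(bad, cl), "violated")
  expect_equal(is_monophyletic(good, clade_definition("A", c("a1", "zz"))),
               "not_evaluable")
  # whole leaf set is trivially monophyletic
  expect_equal(is_monophyletic(good,
               clade_definition("all", c("a1", "a2", "b1", "b2"))),
               "monophyletic")
  expect_error(clade_definition("A", c("a1", "a2"), min_present = 1))
})

test_that("monophyly equals exhaustive edge-deletion enumeration on small trees", {
  set.seed(19)
  for (n in 4:8) {
    for (rep in 1:6) {
      tr <- ape::unroot(ape::rtree(n))
      tips <- tr$tip.label
      splits <- igraph_splits(tr)
      subsets <- unlist(lapply(2:n, function(k)
        utils::combn(tips, k, simplify = FALSE)), recursive = FALSE)
      for (s in subsets) {
        expect_equal(is_monophyletic(tr, clade_definition("s", s)),
                     oracle_monophyly(tr, s, splits = splits),
                     info = paste(n, rep, paste(s, collapse = ",")))
      }
    }
  }
})

test_that("monophyly is invariant under rerooting and leaf-order permutation", {
  set.seed(23)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    s <- sample(tr$tip.label, sample(2:6, 1))
    cl <- clade_definition("s", s)
    v <- is_monophyletic(tr, cl)
    reroot <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                        resolve.root = TRUE)
    expect_equal(is_monophyletic(reroot, cl), v)
    expect_equal(is_monophyletic(ape::ladderize(tr), cl), v)
    expect_equal(is_monophyletic(ape::unroot(tr), cl), v)
  }
})

test_that("marker scores are the fraction of evaluable clades recovered", {
  cfg <- sim_config(seed = 6)
  sp <- simulate_species_tree(cfg)
  clades <- clades_from_taxonomy(sp$taxonomy)
  s <- score_marker(sp$tree, clades, marker_id = "species")
  expect_equal(s$score, 1.0)
  expect_equal(s$n_evaluable, length(clades))

  # exactly 1 of 4 evaluable clades broken -> 0.75
  tr <- read_newick("(((a1:1,a2:1):1,(b1:1,b2:1):1):1,(((c1:1,c2:1):1,d2:1):1,d1:1):1);")
  cls <- list(clade_definition("A", c("a1", "a2")),
              clade_definition("B", c("b1", "b2")),
              clade_definition("C", c("c1", "c2")),
              clade_definition("D", c("d1", "d2")))
  s2 <- score_marker(tr, cls)
  expect_equal(s2$n_evaluable, 4)
  expect_equal(s2$per_clade[["D"]], "violated")
  expect_equal(s2$score, 0.75)
  tr3 <- read_newick("(((a1:1,a2:1):1,(b1:1,b2:1):1):1,((c1:1,c2:1):1,(d1:1,e1:1):1):1);")
  cls3 <- list(clade_definition("A", c("a1", "a2")),
               clade_definition("B", c("b1", "b2")),
               clade_definition("C", c("c1", "c2")),
               clade_definition("D", c("d1", "d2")))  # d2 absent -> not evaluable
  s3 <- score_marker(tr3, cls3)
  expect_equal(s3$n_evaluable, 3)
  expect_equal(s3$score, 1.0)
  broken <- read_newick("(((a1:1,b1:1):1,(a2:1,b2:1):1):1,((c1:1,c2:1):1,(d1:1,d2:1):1):1);")
  s4 <- score_marker(broken, cls)
  expect_equal(s4$score, 0.5)  # A and B violated, C and D intact
})

test_that("ranking is deterministic with documented tie-breaks and nesting", {
  sc <- data.frame(marker_id = c("m4", "m2", "m3", "m1"),
                   n_evaluable = c(5, 5, 5, 5),
                   n_monophyletic = c(5, 5, 5, 5),
                   score = c(1, 1, 1, 1))
  sel <- rank_and_select(sc, 0.5)
  expect_equal(sel$k, 2)
  expect_equal(sel$selected, c("m1", "m2"))  # all tied: lexicographic ids
  expect_error(rank_and_select(sc, 0.5, k_override = 9), "exceeds")
  expect_equal(rank_and_select(sc, 0.5, k_override = 3)$selected,
               c("m1", "m2", "m3"))

  set.seed(37)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    sc <- data.frame(marker_id = sprintf("m%02d", 1:n),
                     n_evaluable = sample(2:8, n, TRUE),
                     n_monophyletic = 0, score = sample(0:4, n, TRUE) / 4)
    s25 <- rank_and_select(sc, 0.25)
    s50 <- rank_and_select(sc, 0.50)
    expect_true(all(s25$selected %in% s50$selected))
    # input order never matters
    perm <- sc[sample(n), ]
    expect_identical(rank_and_select(perm, 0.25)$selected, s25$selected)
  }
})

test_that("clean simulated markers outscore grafted ones and rise in the ranking", {
  cfg <- sim_config(hgt_rate = 0.5, contaminant_rate = 0, n_markers = 200,
                    graft_target = "random", seed = 1)
  sp <- simulate_species_tree(cfg)
  gt <- simulate_gene_trees(sp$tree, sp$taxonomy, cfg)
  clades <- clades_from_taxonomy(sp$taxonomy, roles = c("ingroup", "outgroup"))
  scores <- score_markers(gt$trees, clades)
  clean <- gt$truth$clean[match(scores$marker_id, gt$truth$marker_id)]
  expect_gt(mean(scores$score[clean]), mean(scores$score[!clean]))

  ranking <- rank_and_select(scores, 1.0)$ranking
  top <- ranking[seq_len(50)]
  bottom <- ranking[(length(ranking) - 49):length(ranking)]
  clean_of <- function(ids) mean(gt$truth$clean[match(ids, gt$truth$marker_id)])
  expect_gt(clean_of(top), clean_of(bottom))
})
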