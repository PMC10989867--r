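tend_args <- function(tree) {
  list(tree = tree, taxonomy = toy_taxonomy(),
       groups_a = "Kor", groups_b = "Asg")
}

test_that("sister composition determines the tendency label", {
  with_a <- read_newick("(out:1,((f1:1,f2:1):1,(k1:1,k2:1):1):1,(as1:1,as2:1):1);")
  row <- do.call(classify_tendency, tend_args(with_a))
  expect_equal(row$label, "WITH_A")
  expect_true(row$focal_monophyletic)
  expect_equal(c(row$n_sister_A, row$n_sister_B), c(2L, 0L))

  with_b <- read_newick("(out:1,((f1:1,f2:1):1,(as1:1,as2:1):1):1,(k1:1,k2:1):1);")
  expect_equal(do.call(classify_tendency, tend_args(with_b))$label, "WITH_B")

  # mixed sister at exactly 50/50 stays unresolved under the strict majority
  mixed <- read_newick("(out:1,((f1:1,f2:1):1,(k1:1,as1:1):1):1,(k2:1,as2:1):1);")
  expect_equal(do.call(classify_tendency, tend_args(mixed))$label, "UNRESOLVED")

  # broken focal clade is unresolved, not majority-voted
  broken <- read_newick("(out:1,((f1:1,k1:1):1,(f2:1,k2:1):1):1,(as1:1,as2:1):1);")
  rowb <- do.call(classify_tendency, tend_args(broken))
  expect_equal(rowb$label, "UNRESOLVED")
  expect_false(rowb$focal_monophyletic)

  # fewer than two focal leaves present is unresolved
  one <- read_newick("(out:1,(f1:1,(k1:1,k2:1):1):1,(as1:1,as2:1):1);")
  expect_equal(do.call(classify_tendency, tend_args(one))$label, "UNRESOLVED")

  tax_nofocal <- toy_taxonomy()
  tax_nofocal$role[tax_nofocal$role == "focal"] <- "ingroup"
  expect_error(classify_tendency(with_a, tax_nofocal, "Kor", "Asg"),
               "no focal")
})

test_that("tendency is invariant to leaf order and rooting detail", {
  base <- read_newick("(out:1,((f1:1,f2:1):1,(k1:1,k2:1):1):1,(as1:1,as2:1):1);")
  v <- do.call(classify_tendency, tend_args(base))$label
  expect_equal(do.call(classify_tendency, tend_args(ape::ladderize(base)))$label, v)
  rot <- read_newick(write_newick(ape::rotate(ape::root(base, "as1",
                                                        resolve.root = TRUE), 9)))
  expect_equal(do.call(classify_tendency, tend_args(rot))$label, v)
  # midpoint fallback (no outgroup leaf in the tree) gives the same call here
  noout <- ape::drop.tip(base, "out")
  expect_equal(do.call(classify_tendency, tend_args(noout))$label, v)
})

test_that("labels recover simulated graft groups exactly when grafts are forced", {
  cfg <- sim_config(hgt_rate = 1, contaminant_rate = 0, graft_target = "B",
                    n_markers = 40, seed = 14)
  sp <- simulate_species_tree(cfg)
  gt <- simulate_gene_trees(sp$tree, sp$taxonomy, cfg)
  ga <- grep("^A", unique(sp$taxonomy$clade), value = TRUE)
  gb <- grep("^B", unique(sp$taxonomy$clade), value = TRUE)
  tt <- classify_tendencies(gt$trees, sp$taxonomy, ga, gb)
  expect_true(all(tt$label == "WITH_B"))

  # without discordance the label reflects the species-tree position
  cfg0 <- sim_config(hgt_rate = 0, contaminant_rate = 0, n_markers = 5, seed = 14)
  gt0 <- simulate_gene_trees(sp$tree, sp$taxonomy, cfg0)
  tt0 <- classify_tendencies(gt0$trees, sp$taxonomy, ga, gb)
  expect_true(all(tt0$label == "WITH_B"))
})

test_that("venn regions partition the union with correct percentages", {
  tend <- data.frame(marker_id = c("x", "y", "z"),
                     label = c("WITH_B", "WITH_A", "WITH_A"))
  vr <- venn_overlap(list(S1 = c("x", "y"), S2 = "z"), tend)
  expect_false(any(vr$region == "S1&S2"))  # disjoint sets: no overlap region
  expect_equal(sum(vr$n), 3)
  expect_equal(vr$pct_with_B[vr$region == "S1"], 50.0)

  expect_error(venn_overlap(list(S1 = c("x", "q")), tend), "2")
  expect_error(venn_overlap(list(S1 = c("x", "q"), S2 = "y"), tend), "q")
})

test_that("venn region sizes agree with a brute-force signature partition", {
  set.seed(41)
  pool <- sprintf("m%03d", 1:40)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(j) sample(pool, sample(3:25, 1)))
    names(sets) <- paste0("S", seq_len(k))
    tend <- data.frame(marker_id = pool,
                       label = sample(c("WITH_A", "WITH_B", "UNRESOLVED"),
                                      40, TRUE))
    vr <- venn_overlap(sets, tend)
    expect_equal(sum(vr$n), length(unique(unlist(sets))))
    expect_true(all(vr$pct_with_B >= 0 & vr$pct_with_B <= 100))
    # brute force: every membership signature via set algebra
    for (sig in seq_len(2^k - 1)) {
      inn <- as.logical(bitwAnd(sig, 2^(seq_len(k) - 1)))
      ids <- Reduce(intersect, sets[inn])
      for (s in sets[!inn]) ids <- setdiff(ids, s)
      key <- paste(names(sets)[inn], collapse = "&")
      got <- vr$n[vr$region == key]
      expect_equal(if (length(got)) got else 0L, length(ids), info = key)
    }
  }
})
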