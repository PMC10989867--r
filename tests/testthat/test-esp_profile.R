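test_that("presence-absence matrices reflect hit tables", {
  empty <- data.frame(genome_id = character(), family_id = character())
  m0 <- build_matrix(empty, families = c("f1", "f2", "f3"),
                     genomes = c("g1", "g2"))
  expect_true(all(m0 == 0) && all(dim(m0) == c(2, 3)))

  one <- data.frame(genome_id = "g1", family_id = "f2")
  m1 <- build_matrix(one, families = c("f1", "f2", "f3"),
                     genomes = c("g1", "g2"))
  expect_equal(sum(m1), 1)
  expect_equal(m1["g1", "f2"], 1L)

  dupes <- data.frame(genome_id = c("g1", "g1"), family_id = c("f1", "f1"),
                      n_copies = c(1L, 3L))
  expect_equal(sum(build_matrix(dupes)), 1)  # merged, not errored

  set.seed(61)
  for (i in 1:20) {
    hits <- data.frame(genome_id = sample(paste0("g", 1:6), 30, TRUE),
                       family_id = sample(paste0("f", 1:8), 30, TRUE))
    m <- build_matrix(hits)
    byg <- tapply(hits$family_id, hits$genome_id,
                  function(x) length(unique(x)))
    expect_equal(unname(rowSums(m)[names(byg)]), as.numeric(byg))
  }
})

test_that("profile distances match independent set computations", {
  m <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 1, 0, 0), g3 = c(0, 0, 1, 1),
             g4 = c(0, 0, 0, 0), g5 = c(0, 0, 0, 0))
  d <- profile_distance(m, "jaccard")
  expect_equal(d["g1", "g2"], 0)
  expect_equal(d["g1", "g3"], 1)     # disjoint nonempty profiles
  expect_equal(d["g4", "g5"], 0)     # both all-zero: defined as 0
  expect_true(isSymmetric(d) && all(diag(d) == 0))

  set.seed(62)
  for (i in 1:20) {
    m <- matrix(rbinom(40, 1, 0.4), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("f", 1:8)))
    dj <- profile_distance(m, "jaccard")
    dh <- profile_distance(m, "hamming")
    for (a in 1:4) for (b in (a + 1):5) {
      A <- which(m[a, ] == 1); B <- which(m[b, ] == 1)
      u <- length(union(A, B))
      expect_equal(dj[a, b], if (u == 0) 0 else 1 - length(intersect(A, B)) / u)
      expect_equal(dh[a, b], sum(xor(m[a, ], m[b, ])) / ncol(m))
    }
  }
})

test_that("upgma merges by definition with deterministic tie-breaks", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  dd <- upgma(d2)
  expect_equal(dd$heights, 0.2)
  expect_equal(unname(cophenetic_distances(dd)["a", "b"]), 0.4)

  d3 <- matrix(0.6, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  dd3 <- upgma(d3)  # equidistant: first merge is (a,b) by index tie-break
  expect_equal(dd3$heights, c(0.3, 0.3))
  expect_true(same_topology(dd3$tree,
                            read_newick("((a:1,b:1):1,c:1);")))

  bad <- d3; bad[1, 2] <- 0.1
  expect_error(upgma(bad), "symmetric")
})

test_that("upgma is ultrametric and matches average-linkage recomputation", {
  set.seed(63)
  for (i in 1:20) {
    d <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
    d[lower.tri(d)] <- runif(15, 0.1, 1)
    d <- d + t(d)
    dd <- upgma(d)
    depths <- ape::node.depth.edgelength(dd$tree)
    expect_equal(max(abs(depths[1:6] - max(dd$heights))), 0, tolerance = 1e-9)
    expect_true(all(diff(dd$heights) >= -1e-12))
    # brute-force recomputation through stats::hclust average linkage
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(cophenetic_distances(dd)[paste0("g", 1:6), paste0("g", 1:6)],
                 as.matrix(stats::cophenetic(hc))[paste0("g", 1:6), paste0("g", 1:6)],
                 tolerance = 1e-9)
  }
})

test_that("disjoint family repertoires split first in the dendrogram", {
  fams <- paste0("f", 1:10)
  hits <- rbind(
    expand.grid(genome_id = paste0("x", 1:3), family_id = fams[1:5]),
    expand.grid(genome_id = paste0("y", 1:3), family_id = fams[6:10]))
  hits[] <- lapply(hits, as.character)
  m <- build_matrix(hits)
  dd <- upgma(profile_distance(m, "jaccard"))
  root_children <- phangorn::Descendants(
    dd$tree, dd$tree$edge[dd$tree$edge[, 1] == ape::Ntip(dd$tree) + 1L, 2],
    type = "tips")
  sides <- lapply(root_children, function(i) sort(dd$tree$tip.label[i]))
  expect_true(setequal(sides, list(paste0("x", 1:3), paste0("y", 1:3))))

  # genome-order permutation yields an isomorphic dendrogram: identical
  # cophenetic distances (nesting within tied zero-distance groups may vary)
  set.seed(64)
  perm <- sample(rownames(m))
  dd2 <- upgma(profile_distance(m[perm, ], "jaccard"))
  ids <- rownames(m)
  expect_equal(cophenetic_distances(dd2)[ids, ids],
               cophenetic_distances(dd)[ids, ids], tolerance = 1e-12)
})
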